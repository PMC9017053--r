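#' Configuration for recursive model-based clustering
#'
#' @param min_cluster_fraction Minimum size of a meaningful cluster as a
#'   fraction of the whole cohort (default 0.01: a proposed child smaller
#'   than 1% of all samples is treated as a set of outliers and merged back
#'   into its nearest accepted sibling instead of founding a subtype).
#' @param max_components Upper bound of the BIC search over mixture
#'   component counts at each node (default 9).
#' @param model_names Covariance families searched by [mclust::Mclust];
#'   defaults to the spherical and diagonal families, which remain
#'   well-posed when features outnumber samples (the gene-motif matrix is
#'   wide). One-dimensional node projections automatically use the
#'   univariate families `E`/`V`.
#' @param min_feature_fraction For binary (0/1) feature matrices: a
#'   feature is used at a node only when its carrier fraction among the
#'   node's samples lies in `[min_feature_fraction, 1 -
#'   min_feature_fraction]` (default 0.05). Features mutated in under 5%
#'   of a node's samples reflect the sporadic background-mutation rate,
#'   not cluster structure at that node's scale; filtering them per node
#'   keeps the projection from chasing background noise. Ignored for
#'   non-binary matrices.
#' @param n_pcs Number of leading principal components of each node's
#'   re-standardized feature matrix on which that node's mixture is fitted
#'   (default 1: principal-direction divisive partitioning). Each node is
#'   projected afresh, so the dominant contrast of the whole cohort drives
#'   the first split and the dominant contrast *within* each cluster
#'   drives its own split — this is what makes the recursion multi-level
#'   rather than a re-run of the same flat clustering.
#' @param max_depth Maximum recursion depth (default 4).
#' @param seed Integer seed (the GMM initialization is deterministic, but
#'   the seed also covers any stochastic restarts).
#' @return A list of class `"clustering_config"`.
#' @export
clustering_config <- function(min_cluster_fraction = 0.01,
                              max_components = 9,
                              model_names = c("EII", "VII", "EEI", "VEI",
                                              "EVI", "VVI"),
                              min_feature_fraction = 0.05,
                              n_pcs = 1,
                              max_depth = 4,
                              seed = 1L) {
  stopifnot(min_cluster_fraction > 0, min_cluster_fraction < 1,
            max_components >= 1, max_depth >= 1, n_pcs >= 1,
            min_feature_fraction >= 0, min_feature_fraction < 0.5)
  structure(list(min_cluster_fraction = min_cluster_fraction,
                 max_components = max_components,
                 model_names = model_names,
                 min_feature_fraction = min_feature_fraction,
                 n_pcs = as.integer(n_pcs),
                 max_depth = max_depth,
                 seed = as.integer(seed)),
            class = "clustering_config")
}

#' Standardize the clustering feature matrix
#'
#' Columns are centered and scaled to unit variance; zero-variance columns
#' carry no information and are dropped (with a message naming how many).
#'
#' @param matrix Numeric matrix (samples x features), typically the
#'   binarized gene-motif matrix.
#' @return Dense standardized matrix.
#' @export
preprocess_features <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty feature matrix")
  v <- apply(m, 2, stats::var)
  drop <- v == 0 | is.na(v)
  if (any(drop)) {
    message("preprocess_features: dropping ", sum(drop),
            " zero-variance column(s)")
    m <- m[, !drop, drop = FALSE]
  }
  if (ncol(m) == 0) stop("all columns have zero variance")
  scale(m)
}

#' Fit a Gaussian mixture and select the number of components by BIC
#'
#' Searches component counts `1:max_components` across the configured
#' covariance families and keeps the model with the best BIC. The mclust
#' initialization (model-based agglomerative hierarchical start) is
#' deterministic, so repeated runs agree.
#'
#' @param x Preprocessed numeric matrix (samples x features).
#' @param config A [clustering_config()].
#' @return The fitted `Mclust` object.
#' @export
fit_gmm_select <- function(x, config = clustering_config()) {
  g_max <- min(config$max_components, nrow(x) - 1L)
  model_names <- if (ncol(x) == 1L) c("E", "V") else config$model_names
  fit <- withr::with_seed(config$seed, {
    Mclust(x, G = 1:max(1L, g_max),
           modelNames = model_names, verbose = FALSE)
  })
  if (is.null(fit)) stop("mclust failed to fit any model")
  fit
}

node_id_counter <- function() {
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
}

#' Recursive model-based clustering with a meaningfulness rule
#'
#' Implements the multi-level subtype search by principal-direction
#' divisive partitioning: at each node the node's samples are
#' re-standardized on the features that still vary there, projected onto
#' the node's `n_pcs` leading principal components, and a Gaussian mixture
#' with BIC-selected component count is fitted to that projection; each
#' resulting cluster is then treated the same way, recursively. Because
#' every node is projected afresh, the first split follows the dominant
#' axis of variation of the whole cohort while deeper splits follow the
#' dominant axis *within* each cluster — the mechanism that yields
#' coarse-to-fine, multi-level structure. (A full-dimensional BIC search
#' is scale-invariant: a refinement it accepts inside a cluster it would
#' already have accepted at the root, so it cannot produce a two-level
#' hierarchy on separable data.)
#'
#' A proposed split is accepted only when at least two of its children
#' reach the meaningful-cluster floor (`min_cluster_fraction` of the
#' *whole cohort*). Children below the floor do not found subtypes: their
#' samples are treated as outliers and merged into the nearest accepted
#' sibling, measured by Mahalanobis distance to the sibling's mixture
#' component. Recursion stops when a node's proposed split is rejected,
#' the node is too small to split, or `max_depth` is reached.
#'
#' @param matrix Binarized gene-motif matrix (samples x features); rows must
#'   be named by sample id.
#' @param config A [clustering_config()].
#' @return A list of class `"cluster_tree"`; each node carries `node_id`,
#'   `sample_ids`, `depth`, `outliers` (samples merged back at this node's
#'   split), model summary (`G`, `model_name`, `bic`) and `children`.
#' @export
recursive_cluster <- function(matrix, config = clustering_config()) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  floor_n <- max(2L, ceiling(config$min_cluster_fraction * nrow(m)))
  binary_input <- all(m %in% c(0, 1))
  next_id <- node_id_counter()

  # re-standardize, filter and project one node's samples
  node_projection <- function(rows) {
    sub <- m[rows, , drop = FALSE]
    if (binary_input && config$min_feature_fraction > 0) {
      frac <- colMeans(sub)
      keep <- frac >= config$min_feature_fraction &
        frac <= 1 - config$min_feature_fraction
      sub <- sub[, keep, drop = FALSE]
    }
    v <- apply(sub, 2, stats::var)
    sub <- sub[, v > 0, drop = FALSE]
    if (ncol(sub) == 0) return(NULL)
    sub <- scale(sub)
    npc <- min(config$n_pcs, ncol(sub), nrow(sub) - 1L)
    pc <- stats::prcomp(sub, center = FALSE)
    pc$x[, seq_len(npc), drop = FALSE]
  }

  # would this pair of sample sets be recognized as two clusters on its
  # own? (the same analysis the recursion applies to any node)
  pair_is_split <- function(rows) {
    proj <- node_projection(rows)
    if (is.null(proj)) return(FALSE)
    cfg2 <- config
    cfg2$max_components <- 2
    fit <- tryCatch(fit_gmm_select(proj, cfg2), error = function(e) NULL)
    !is.null(fit) && fit$G == 2
  }

  cluster_node <- function(rows, depth) {
    node <- list(node_id = next_id(), sample_ids = rownames(m)[rows],
                 depth = depth, size = length(rows),
                 outliers = character(0), children = list(),
                 G = NA_integer_, model_name = NA_character_,
                 bic = NA_real_)
    if (depth >= config$max_depth || length(rows) < 2L * floor_n) {
      return(node)
    }
    sub <- node_projection(rows)
    if (is.null(sub)) return(node)
    fit <- tryCatch(fit_gmm_select(sub, config), error = function(e) NULL)
    if (is.null(fit)) return(node)
    node$G <- fit$G
    node$model_name <- fit$modelName
    node$bic <- unname(fit$bic)
    cls <- fit$classification
    sizes <- tabulate(cls, nbins = fit$G)
    big <- which(sizes >= floor_n)
    if (fit$G < 2 || length(big) < 2) {
      return(node)   # no meaningful split: terminal subtype
    }
    small <- setdiff(seq_len(fit$G), big)
    if (length(small) > 0) {
      # Mahalanobis distance of each outlier sample to each accepted
      # component (diagonal covariance; univariate fits store a vector
      # mean and sigmasq instead of matrices)
      mu <- fit$parameters$mean
      if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
      var_of <- function(g) {
        v <- fit$parameters$variance
        if (!is.null(v$sigma)) {
          if (length(dim(v$sigma)) == 3) diag(v$sigma[, , g])
          else diag(as.matrix(v$sigma))
        } else if (!is.null(v$sigmasq)) {
          rep_len(if (length(v$sigmasq) >= g) v$sigmasq[g] else v$sigmasq,
                  nrow(mu))
        } else rep(1, nrow(mu))
      }
      for (s in small) {
        idx <- which(cls == s)
        for (i in idx) {
          d2 <- vapply(big, function(g) {
            dv <- sub[i, ] - mu[, g]
            sum(dv^2 / pmax(var_of(g), 1e-8))
          }, numeric(1))
          cls[i] <- big[which.min(d2)]
        }
        node$outliers <- c(node$outliers, rownames(sub)[idx])
      }
    }
    groups <- lapply(big, function(g) rows[cls == g])
    # validate siblings pairwise: two accepted children that the same
    # node analysis would not recognize as two clusters on their own are
    # one cluster that the mixture over-segmented; merge them back
    repeat {
      merged <- FALSE
      if (length(groups) >= 2) {
        for (i in seq_len(length(groups) - 1)) {
          for (j in (i + 1):length(groups)) {
            if (!pair_is_split(c(groups[[i]], groups[[j]]))) {
              groups[[i]] <- c(groups[[i]], groups[[j]])
              groups[[j]] <- NULL
              merged <- TRUE
              break
            }
          }
          if (merged) break
        }
      }
      if (!merged) break
    }
    if (length(groups) < 2) return(node)   # split did not survive validation
    node$children <- lapply(groups, function(rr) {
      cluster_node(rr, depth + 1L)
    })
    node
  }

  tree <- cluster_node(seq_len(nrow(m)), 0L)
  structure(list(root = tree, floor = floor_n, n = nrow(m),
                 config = config),
            class = "cluster_tree")
}

tree_leaves <- function(node) {
  if (length(node$children) == 0) return(list(node))
  do.call(c, lapply(node$children, tree_leaves))
}

#' @export
print.cluster_tree <- function(x, ...) {
  leaves <- tree_leaves(x$root)
  cat("recursive clustering of", x$n, "samples ->", length(leaves),
      "terminal subtype(s); meaningful-cluster floor =", x$floor, "\n")
  show_node <- function(node, indent) {
    cat(strrep("  ", indent), "node ", node$node_id, ": n = ", node$size,
        if (length(node$children) == 0) "  [subtype]" else
          sprintf("  (G = %d, %s)", node$G, node$model_name),
        "\n", sep = "")
    for (ch in node$children) show_node(ch, indent + 1)
  }
  show_node(x$root, 0)
  invisible(x)
}

#' Label terminal subtypes SC1..SCm
#'
#' Leaves are labeled deterministically: ordered by their first-level
#' ancestor (in fitted component order), then by decreasing size within it.
#'
#' @param tree A `"cluster_tree"` from [recursive_cluster()].
#' @return Data.frame (sample_id, subtype, level1, outlier) with one row per
#'   sample; `outlier` marks samples merged back into their subtype by the
#'   meaningfulness rule.
#' @export
assign_subtypes <- function(tree) {
  root <- tree$root
  first_level <- if (length(root$children) == 0) list(root) else root$children
  leaf_groups <- lapply(first_level, tree_leaves)
  out <- list()
  label <- 0L
  for (li in seq_along(leaf_groups)) {
    leaves <- leaf_groups[[li]]
    ord <- order(-vapply(leaves, function(l) l$size, 0))
    for (leaf in leaves[ord]) {
      label <- label + 1L
      out[[label]] <- data.frame(sample_id = leaf$sample_ids,
                                 subtype = paste0("SC", label),
                                 level1 = li,
                                 stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  outliers <- unlist(collect_outliers(root))
  res$outlier <- res$sample_id %in% outliers
  rownames(res) <- NULL
  res
}

collect_outliers <- function(node) {
  c(list(node$outliers), lapply(node$children, collect_outliers))
}

#' PCA projection of the feature matrix
#'
#' Centered principal-component projection used to inspect feature quality
#' (e.g. whether planted or real subtypes separate in the first components).
#' Inspection only: the clustering itself runs on the full standardized
#' matrix.
#'
#' @param matrix Numeric matrix (samples x features).
#' @param n_components Number of components to return (default 2).
#' @param scale. Scale columns to unit variance first (default FALSE).
#' @return List with `coordinates` (samples x n_components),
#'   `explained_variance` (proportions, all components) and `sdev`.
#' @export
pca_project <- function(matrix, n_components = 2, scale. = FALSE) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (scale.) {
    v <- apply(m, 2, stats::var)
    m <- m[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = scale.)
  nc <- min(n_components, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(nc), drop = FALSE],
       explained_variance = pc$sdev^2 / sum(pc$sdev^2),
       sdev = pc$sdev)
}

#' Serialize a cluster tree to JSON
#' @param tree A `"cluster_tree"`.
#' @param path Output file.
#' @export
write_cluster_tree <- function(tree, path) {
  strip <- function(node) {
    list(node_id = node$node_id, depth = node$depth, size = node$size,
         G = node$G, model_name = node$model_name, bic = node$bic,
         sample_ids = node$sample_ids, outliers = node$outliers,
         children = lapply(node$children, strip))
  }
  jsonlite::write_json(list(n = tree$n, floor = tree$floor,
                            root = strip(tree$root)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
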