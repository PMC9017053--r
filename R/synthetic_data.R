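#' Configuration for a synthetic mutation cohort
#'
#' Defines the study conditions the generator emulates: a cohort with a
#' planted two-level subtype structure (subtypes grouped into
#' super-clusters), negative-binomial per-gene background mutation counts,
#' Bernoulli-planted enriched gene-motifs with beta-binomial-like
#' overdispersion at the cohort level, subtype-linked clinical covariates
#' and exponential survival with censoring.
#'
#' @param n_samples Cohort size (default 533, the sum of the default
#'   subtype sizes).
#' @param subtype_sizes Planted subtype sizes (default
#'   `c(44, 137, 64, 205, 13, 49, 21)`).
#' @param superclusters List of integer vectors grouping subtype indices
#'   into first-level super-clusters (default
#'   `list(1:4, 5:7)`); must partition `seq_along(subtype_sizes)`.
#' @param n_genes,n_lncrna Numbers of coding and lncRNA genes (default 500
#'   each).
#' @param n_driver_genes Size of the coding driver-gene pool from which all
#'   planted gene-motifs draw their genes (default 40); sharing genes
#'   across subtypes reproduces the observation that the same gene can be
#'   significant in several subtypes with different motif contexts.
#' @param background_nb_mean,background_nb_dispersion Mean and size
#'   (dispersion) of the negative-binomial law for per-gene mutated-sample
#'   counts on background genes (defaults 8 and 1.5: most genes are mutated
#'   in a few percent of samples, with a long overdispersed tail).
#' @param driver_background_mean,driver_background_dispersion
#'   Negative-binomial mean and size for per-gene mutated-sample counts on
#'   driver-pool genes (defaults 150 and 10): frequently mutated genes are
#'   frequently mutated everywhere, not only at their enriched contexts, so
#'   their background spreads across all 96 substitution channels as in
#'   real highly mutated cancer genes.
#' @param enriched_motifs_per_subtype Planted gene-motif features per
#'   subtype (default 30).
#' @param enrichment_prob Probability that a subtype member carries each of
#'   its subtype's enriched gene-motifs (default 0.8).
#' @param background_motif_prob Probability that a non-member carries an
#'   enriched gene-motif (default 0.02).
#' @param supercluster_motifs,supercluster_prob Shared enriched gene-motifs
#'   per super-cluster and their carrier probability (defaults 30 and 0.9);
#'   these features make the planted hierarchy genuinely two-level: the
#'   first clustering level separates super-clusters, the second separates
#'   subtypes.
#' @param hyper_subtype Index of a hyper-mutated subtype whose members are
#'   preferentially hit by background mutations (default 5, weight
#'   `hyper_weight = 5`); set `NA` to disable.
#' @param hyper_weight Sampling weight multiplier for hyper-subtype members
#'   in the background draw (default 5).
#' @param intergenic_rate Mean number of intergenic mutations per sample
#'   (Poisson, default 30).
#' @param male_prob,china_prob Per-subtype probabilities of male sex and of
#'   Chinese origin (recycled to the number of subtypes).
#' @param age_mean,age_sd Per-subtype age distribution (normal).
#' @param hazard Per-subtype exponential death hazards per day; the default
#'   gives one subtype a clearly better and one a clearly worse outcome.
#' @param censor_max Administrative censoring horizon: censoring times are
#'   uniform on (0, censor_max) days (default 2000).
#' @param transcript_bias Probability that a planted mutation in a coding
#'   driver gene is assigned to the gene's first transcript (default 0.9),
#'   planting transcript-level enrichment.
#' @param consequence_probs Named vector of global consequence-type mixture
#'   weights for in-gene mutations (intergenic mutations are always
#'   `"intergenic_region"`).
#' @param n_chroms,chrom_len,seed Reference geometry and master seed.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 533,
                          subtype_sizes = c(44, 137, 64, 205, 13, 49, 21),
                          superclusters = list(1:4, 5:7),
                          n_genes = 500,
                          n_lncrna = 500,
                          n_driver_genes = 40,
                          background_nb_mean = 8,
                          background_nb_dispersion = 1.5,
                          driver_background_mean = 150,
                          driver_background_dispersion = 10,
                          enriched_motifs_per_subtype = 30,
                          enrichment_prob = 0.8,
                          background_motif_prob = 0.02,
                          supercluster_motifs = 30,
                          supercluster_prob = 0.9,
                          hyper_subtype = 5,
                          hyper_weight = 5,
                          intergenic_rate = 30,
                          male_prob = c(0.55, 0.50, 0.61, 0.55, 0.77,
                                        0.55, 0.48),
                          china_prob = c(0.10, 0.10, 0.10, 0.10, 0.10,
                                         0.10, 1.00),
                          age_mean = c(66, 60, 66, 66, 72, 66, 66),
                          age_sd = 10,
                          hazard = c(1 / 1200, 1 / 1200, 1 / 2400, 1 / 1200,
                                     1 / 1000, 1 / 1200, 1 / 400),
                          censor_max = 2000,
                          transcript_bias = 0.9,
                          consequence_probs = NULL,
                          n_chroms = 4,
                          chrom_len = 450000,
                          seed = 42L) {
  if (sum(subtype_sizes) != n_samples) {
    stop("sum(subtype_sizes) must equal n_samples (",
         sum(subtype_sizes), " != ", n_samples, ")")
  }
  if (any(subtype_sizes <= 0)) stop("subtype sizes must be positive")
  sc <- sort(as.integer(unlist(superclusters)))
  if (!identical(sc, seq_along(subtype_sizes))) {
    stop("superclusters must partition the subtype indices")
  }
  probs <- c(enrichment_prob, background_motif_prob, supercluster_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (background_nb_mean <= 0 || background_nb_dispersion <= 0) {
    stop("negative-binomial parameters must be positive")
  }
  ns <- length(subtype_sizes)
  if (is.null(consequence_probs)) {
    consequence_probs <- c(
      intron_variant = 0.24, downstream_gene_variant = 0.17,
      missense_variant = 0.18, upstream_gene_variant = 0.12,
      exon_variant = 0.09, synonymous_variant = 0.09,
      "3_prime_UTR_variant" = 0.03, splice_region_variant = 0.012,
      stop_gained = 0.015, "5_prime_UTR_variant" = 0.007,
      splice_acceptor_variant = 0.003, splice_donor_variant = 0.003,
      "5_prime_UTR_premature_start_codon_gain_variant" = 0.002,
      start_lost = 0.0003, stop_lost = 0.0002,
      stop_retained_variant = 0.0001, initiator_codon_variant = 0.0001)
    consequence_probs <- consequence_probs / sum(consequence_probs)
  }
  structure(list(
    n_samples = n_samples, subtype_sizes = subtype_sizes,
    superclusters = superclusters, n_genes = n_genes, n_lncrna = n_lncrna,
    n_driver_genes = n_driver_genes,
    background_nb_mean = background_nb_mean,
    background_nb_dispersion = background_nb_dispersion,
    driver_background_mean = driver_background_mean,
    driver_background_dispersion = driver_background_dispersion,
    enriched_motifs_per_subtype = enriched_motifs_per_subtype,
    enrichment_prob = enrichment_prob,
    background_motif_prob = background_motif_prob,
    supercluster_motifs = supercluster_motifs,
    supercluster_prob = supercluster_prob,
    hyper_subtype = hyper_subtype, hyper_weight = hyper_weight,
    intergenic_rate = intergenic_rate,
    male_prob = rep_len(male_prob, ns),
    china_prob = rep_len(china_prob, ns),
    age_mean = rep_len(age_mean, ns), age_sd = age_sd,
    hazard = rep_len(hazard, ns), censor_max = censor_max,
    transcript_bias = transcript_bias,
    consequence_probs = consequence_probs,
    n_chroms = n_chroms, chrom_len = chrom_len,
    seed = as.integer(seed)),
    class = "cohort_config")
}

#' Generate a toy reference genome with non-overlapping gene models
#'
#' Uniform-random ACGT sequence with `n_genes + n_lncrna` non-overlapping
#' gene bodies distributed round-robin over the chromosomes, each coding
#' gene carrying 1-3 nested transcripts. Deterministic given the seed.
#'
#' @param n_chroms,chrom_len Reference geometry (chrom_len >= 3).
#' @param seed Integer seed.
#' @param n_genes,n_lncrna Gene counts by biotype.
#' @param gene_length Min/max gene body length (default 900-1500 bp).
#' @param margin Gene-free margin at each chromosome end (default 500 bp).
#' @return List: `reference` ([Biostrings::DNAStringSet]), `genes`,
#'   `transcripts` (data.frames as from [read_genes()]).
#' @export
generate_reference <- function(n_chroms, chrom_len, seed = 1L,
                               n_genes = 500, n_lncrna = 500,
                               gene_length = c(900, 1500), margin = 500) {
  if (n_chroms < 1 || chrom_len < 3) {
    stop("need n_chroms >= 1 and chrom_len >= 3")
  }
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste(sample(bases, chrom_len, replace = TRUE), collapse = "")
    }, character(1))
    chrom_names <- paste0("chr", seq_len(n_chroms))
    reference <- Biostrings::DNAStringSet(seqs)
    names(reference) <- chrom_names

    ng <- n_genes + n_lncrna
    genes <- NULL
    transcripts <- NULL
    if (ng > 0) {
      usable <- chrom_len - 2 * margin
      if (usable < gene_length[1]) {
        stop("chrom_len too small to host the requested genes")
      }
      biotype <- sample(c(rep("coding", n_genes), rep("lncRNA", n_lncrna)))
      chrom_of <- rep_len(seq_len(n_chroms), ng)
      rows <- vector("list", ng)
      cursor <- rep(margin + 1L, n_chroms)
      for (g in seq_len(ng)) {
        ch <- chrom_of[g]
        len <- sample(gene_length[1]:gene_length[2], 1L)
        gap <- sample(50:250, 1L)
        start <- cursor[ch]
        end <- start + len - 1L
        if (end > chrom_len - margin) {
          stop("chrom_len too small to host the requested genes ",
               "(ran out of room on ", chrom_names[ch], ")")
        }
        cursor[ch] <- end + gap
        rows[[g]] <- data.frame(
          gene_id = sprintf("%s%04d",
                            if (biotype[g] == "coding") "GENE" else "LNC",
                            g),
          name = sprintf("%s%04d",
                         if (biotype[g] == "coding") "GENE" else "LNC", g),
          biotype = biotype[g],
          chrom = chrom_names[ch], start = start, end = end,
          strand = sample(c("+", "-"), 1L),
          stringsAsFactors = FALSE)
      }
      genes <- do.call(rbind, rows)
      tx <- list()
      for (g in which(genes$biotype == "coding")) {
        ntx <- sample(1:3, 1L)
        glen <- genes$end[g] - genes$start[g] + 1L
        for (j in seq_len(ntx)) {
          off5 <- if (j == 1) 0L else sample(0:floor(glen * 0.2), 1L)
          off3 <- if (j == 1) 0L else sample(0:floor(glen * 0.2), 1L)
          tx[[length(tx) + 1]] <- data.frame(
            transcript_id = sprintf("TX%s.%d", genes$gene_id[g], j),
            gene_id = genes$gene_id[g],
            chrom = genes$chrom[g],
            start = genes$start[g] + off5,
            end = genes$end[g] - off3,
            strand = genes$strand[g],
            stringsAsFactors = FALSE)
        }
      }
      transcripts <- if (length(tx) > 0) do.call(rbind, tx) else NULL
    }
    if (is.null(genes)) {
      genes <- data.frame(gene_id = character(), name = character(),
                          biotype = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE)
    }
    if (is.null(transcripts)) {
      transcripts <- data.frame(transcript_id = character(),
                                gene_id = character(), chrom = character(),
                                start = integer(), end = integer(),
                                strand = character(),
                                stringsAsFactors = FALSE)
    }
    list(reference = reference, genes = genes, transcripts = transcripts)
  })
}

#' Positions inside a gene whose trinucleotide context matches a class
#'
#' A motif class with pyrimidine context `ctx` is realizable at +-strand
#' positions where the reference 3-mer equals `ctx` (mutate on the +
#' strand) or `revcomp(ctx)` (the pyrimidine sits on the - strand).
#' @return Data.frame (pos, on_plus) of mutable middle-base positions, or
#'   zero rows when the gene lacks the context.
#' @noRd
motif_positions_in_gene <- function(reference, chrom, start, end, ctx) {
  seq <- Biostrings::subseq(reference[[chrom]], start, end)
  plus <- Biostrings::start(Biostrings::matchPattern(ctx, seq))
  rc <- revcomp(ctx)
  minus <- if (rc == ctx) integer(0) else
    Biostrings::start(Biostrings::matchPattern(rc, seq))
  # relative match start r => absolute 3-mer start = start + r - 1,
  # mutable middle base = start + r
  data.frame(pos = start + c(plus, minus),
             on_plus = rep(c(TRUE, FALSE), c(length(plus), length(minus))))
}

parse_class <- function(class) {
  list(p5 = substr(class, 1, 1), ref = substr(class, 3, 3),
       alt = substr(class, 5, 5), p3 = substr(class, 7, 7),
       ctx = paste0(substr(class, 1, 1), substr(class, 3, 3),
                    substr(class, 7, 7)))
}

#' Generate a synthetic mutation cohort with planted subtype structure
#'
#' Produces a full synthetic study: toy reference and gene models, somatic
#' SNVs combining (i) planted subtype-specific and super-cluster-shared
#' enriched gene-motifs, (ii) negative-binomial per-gene background, and
#' (iii) Poisson intergenic background; a clinical table with
#' subtype-linked sex, country, age and exponential survival; and a truth
#' record (planted labels and enriched features) that downstream pipeline
#' stages never consume.
#'
#' Every emitted mutation's ref allele equals the reference base at its
#' position, and every planted gene-motif mutation sits at a position whose
#' strand-collapsed trinucleotide context realizes the target class.
#'
#' @param config A [cohort_config()].
#' @param reference Optional pre-generated output of [generate_reference()];
#'   generated internally by default.
#' @return A list of class `"synthetic_cohort"`: `reference`, `genes`,
#'   `transcripts`, `mutations` (MAF-lite data.frame), `clinical`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config(), reference = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(reference)) {
    reference <- generate_reference(config$n_chroms, config$chrom_len,
                                    seed = config$seed + 1L,
                                    n_genes = config$n_genes,
                                    n_lncrna = config$n_lncrna)
  }
  genes <- reference$genes
  transcripts <- reference$transcripts
  ref <- reference$reference

  withr::with_seed(config$seed, {
    ns <- length(config$subtype_sizes)
    sample_ids <- sprintf("S%04d", seq_len(config$n_samples))
    truth_subtype <- rep(paste0("T", seq_len(ns)), config$subtype_sizes)
    names(truth_subtype) <- sample_ids
    members <- split(sample_ids, truth_subtype)

    coding <- genes[genes$biotype == "coding", , drop = FALSE]
    if (nrow(coding) < config$n_driver_genes) {
      stop("not enough coding genes for the driver pool")
    }
    driver_pool <- sample(coding$gene_id, config$n_driver_genes)

    classes <- motif_classes()
    used_pairs <- character(0)

    plant_features <- function(n_feat, gene_choices, cycle = FALSE) {
      feats <- vector("list", n_feat)
      for (f in seq_len(n_feat)) {
        placed <- FALSE
        for (attempt in 1:50) {
          g <- if (cycle) gene_choices[f] else sample(gene_choices, 1L)
          cl <- sample(classes, 1L)
          pair <- paste(g, cl, sep = "|")
          if (pair %in% used_pairs) next
          gi <- match(g, genes$gene_id)
          pc <- parse_class(cl)
          pos <- motif_positions_in_gene(ref, genes$chrom[gi],
                                         genes$start[gi], genes$end[gi],
                                         pc$ctx)
          if (nrow(pos) == 0) next
          used_pairs <<- c(used_pairs, pair)
          feats[[f]] <- list(gene_id = g, class = cl, positions = pos)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place a realizable gene-motif after 50 attempts; ",
               "reference too small or motif namespace exhausted")
        }
      }
      feats
    }

    # cycle through the driver pool so every driver gene hosts features of
    # several subtypes (same gene, different motif context per subtype)
    subtype_feats <- lapply(seq_len(ns), function(s) {
      nf <- config$enriched_motifs_per_subtype
      offset <- (s - 1L) * nf
      gene_cycle <- driver_pool[((offset + seq_len(nf) - 1L) %%
                                   length(driver_pool)) + 1L]
      plant_features(nf, gene_cycle, cycle = TRUE)
    })
    super_feats <- lapply(seq_along(config$superclusters), function(sc) {
      plant_features(config$supercluster_motifs, driver_pool)
    })

    mut <- list()
    add_mut <- function(sample, chrom, pos, ref_base, alt, gene_id) {
      mut[[length(mut) + 1]] <<- data.frame(
        sample_id = sample, chrom = chrom, pos = pos, ref = ref_base,
        alt = alt, gene_id = gene_id, stringsAsFactors = FALSE)
    }

    emit_feature <- function(feat, carriers) {
      if (length(carriers) == 0) return()
      gi <- match(feat$gene_id, genes$gene_id)
      pc <- parse_class(feat$class)
      pick <- feat$positions[sample.int(nrow(feat$positions),
                                        length(carriers), replace = TRUE), ,
                             drop = FALSE]
      mid <- pick$pos
      ref_base <- ifelse(pick$on_plus, pc$ref, unname(COMPLEMENT[pc$ref]))
      alt <- ifelse(pick$on_plus, pc$alt, unname(COMPLEMENT[pc$alt]))
      add_mut(carriers, genes$chrom[gi], mid, ref_base, alt,
              genes$gene_id[gi])
    }

    for (s in seq_len(ns)) {
      mem <- members[[paste0("T", s)]]
      non <- setdiff(sample_ids, mem)
      for (feat in subtype_feats[[s]]) {
        carriers <- c(mem[stats::runif(length(mem)) <
                            config$enrichment_prob],
                      non[stats::runif(length(non)) <
                            config$background_motif_prob])
        emit_feature(feat, carriers)
      }
    }
    for (sc in seq_along(config$superclusters)) {
      mem <- unlist(members[paste0("T", config$superclusters[[sc]])],
                    use.names = FALSE)
      non <- setdiff(sample_ids, mem)
      for (feat in super_feats[[sc]]) {
        carriers <- c(mem[stats::runif(length(mem)) <
                            config$supercluster_prob],
                      non[stats::runif(length(non)) <
                            config$background_motif_prob])
        emit_feature(feat, carriers)
      }
    }

    # negative-binomial per-gene background: k_g mutated samples per gene,
    # drawn with extra weight on the hyper-mutated subtype's members
    w <- rep(1, config$n_samples)
    if (!is.na(config$hyper_subtype) &&
        config$hyper_subtype <= ns) {
      w[truth_subtype == paste0("T", config$hyper_subtype)] <-
        config$hyper_weight
    }
    is_driver <- genes$gene_id %in% driver_pool
    kg <- stats::rnbinom(nrow(genes), size = config$background_nb_dispersion,
                         mu = config$background_nb_mean)
    kg[is_driver] <- stats::rnbinom(sum(is_driver),
                                    size = config$driver_background_dispersion,
                                    mu = config$driver_background_mean)
    kg <- pmin(kg, config$n_samples)
    for (g in seq_len(nrow(genes))) {
      if (kg[g] == 0) next
      # hyper-mutated members absorb extra background in non-driver genes;
      # driver genes sample uniformly so planted channels stay clean
      hit <- if (is_driver[g]) sample(sample_ids, kg[g])
             else sample(sample_ids, kg[g], prob = w)
      pos <- sample((genes$start[g] + 1L):(genes$end[g] - 1L), kg[g],
                    replace = TRUE)
      ref_base <- toupper(as.character(Biostrings::extractAt(
        ref[[genes$chrom[g]]], IRanges::IRanges(pos, pos))))
      alt <- vapply(ref_base, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
      add_mut(hit, genes$chrom[g], pos, ref_base, unname(alt),
              genes$gene_id[g])
    }

    # intergenic Poisson background
    chrom_names <- names(ref)
    gene_iv <- split(genes[, c("start", "end")], genes$chrom)
    n_inter <- stats::rpois(config$n_samples, config$intergenic_rate)
    for (i in seq_len(config$n_samples)) {
      if (n_inter[i] == 0) next
      ch <- sample(chrom_names, n_inter[i], replace = TRUE)
      for (chn in unique(ch)) {
        cnt <- sum(ch == chn)
        len <- length(ref[[chn]])
        cand <- sample(2:(len - 1L), cnt * 3L, replace = TRUE)
        iv <- gene_iv[[chn]]
        if (!is.null(iv) && nrow(iv) > 0) {
          ing <- vapply(cand, function(p) any(p >= iv$start & p <= iv$end),
                        logical(1))
          cand <- cand[!ing]
        }
        cand <- utils::head(cand, cnt)
        if (length(cand) == 0) next
        ref_base <- toupper(as.character(Biostrings::extractAt(
          ref[[chn]], IRanges::IRanges(cand, cand))))
        alt <- vapply(ref_base, function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
        add_mut(sample_ids[i], chn, cand, ref_base, unname(alt),
                NA_character_)
      }
    }

    mutations <- do.call(rbind, mut)
    # one record per (sample, locus): drop colliding duplicates
    mutations <- mutations[!duplicated(mutations[, c("sample_id", "chrom",
                                                     "pos")]), ,
                           drop = FALSE]

    # consequence types: intergenic fixed, in-gene from the global mixture
    cp <- config$consequence_probs
    conseq <- sample(names(cp), nrow(mutations), replace = TRUE, prob = cp)
    conseq[is.na(mutations$gene_id)] <- "intergenic_region"
    mutations$consequence_type <- conseq

    # transcript assignment for coding-gene mutations; planted driver
    # mutations favor the gene's first transcript (transcript bias)
    mutations$transcript_id <- NA_character_
    if (nrow(transcripts) > 0) {
      tx_by_gene <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
      has_tx <- !is.na(mutations$gene_id) &
        mutations$gene_id %in% names(tx_by_gene)
      for (i in which(has_tx)) {
        txi <- tx_by_gene[[mutations$gene_id[i]]]
        cover <- txi[transcripts$start[txi] <= mutations$pos[i] &
                       transcripts$end[txi] >= mutations$pos[i]]
        if (length(cover) == 0) next
        is_driver <- mutations$gene_id[i] %in% driver_pool
        pick <- if (is_driver && length(cover) > 1 &&
                    stats::runif(1) < config$transcript_bias) {
          cover[1]
        } else if (length(cover) == 1) cover else sample(cover, 1L)
        mutations$transcript_id[i] <- transcripts$transcript_id[pick]
      }
    }
    mutations$gene_id <- NULL
    ord <- order(mutations$sample_id, mutations$chrom, mutations$pos)
    mutations <- mutations[ord, , drop = FALSE]
    rownames(mutations) <- NULL

    # clinical table with subtype-linked covariates
    sub_idx <- match(truth_subtype, paste0("T", seq_len(ns)))
    sex <- ifelse(stats::runif(config$n_samples) <
                    config$male_prob[sub_idx], "male", "female")
    country <- ifelse(stats::runif(config$n_samples) <
                        config$china_prob[sub_idx], "China", "USA")
    age <- round(stats::rnorm(config$n_samples,
                              config$age_mean[sub_idx], config$age_sd))
    age <- pmin(pmax(age, 20), 100)
    t_death <- stats::rexp(config$n_samples,
                           rate = config$hazard[sub_idx])
    t_censor <- stats::runif(config$n_samples, 1, config$censor_max)
    clinical <- data.frame(
      sample_id = sample_ids, sex = sex, country = country, age = age,
      survival_time_days = round(pmin(t_death, t_censor), 1),
      event = as.integer(t_death <= t_censor),
      stringsAsFactors = FALSE)

    feat_df <- function(feats, label) {
      do.call(rbind, lapply(seq_along(feats), function(s) {
        do.call(rbind, lapply(feats[[s]], function(f) {
          data.frame(group = paste0(label, s), gene_id = f$gene_id,
                     motif = f$class,
                     feature = paste(f$gene_id, f$class, sep = "|"),
                     stringsAsFactors = FALSE)
        }))
      }))
    }
    truth <- list(subtype = truth_subtype,
                  supercluster = vapply(sub_idx, function(i) {
                    which(vapply(config$superclusters,
                                 function(g) i %in% g, logical(1)))
                  }, 0L),
                  enriched = feat_df(subtype_feats, "T"),
                  supercluster_enriched = feat_df(super_feats, "SUPER"),
                  driver_pool = driver_pool)
    names(truth$supercluster) <- sample_ids

    structure(list(reference = ref, genes = genes,
                   transcripts = transcripts, mutations = mutations,
                   clinical = clinical, truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", x$config$n_samples, "samples,",
      nrow(x$genes), "genes,", nrow(x$mutations), "mutations\n")
  cat("  planted subtypes:",
      paste(x$config$subtype_sizes, collapse = "/"), "\n")
  invisible(x)
}

#' Write a synthetic cohort to standard file formats
#'
#' Writes `reference.fa` (FASTA), `genes.gtf` (gene + transcript features
#' with a `gene_biotype` attribute), `mutations.tsv` (MAF-lite),
#' `clinical.tsv` and `truth.json` (the planted-structure sidecar, which
#' pipeline stages must never read).
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(cohort$reference,
                              file.path(outdir, "reference.fa"))
  g <- cohort$genes
  tx <- cohort$transcripts
  gr_g <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", source = "genemotif", gene_id = g$gene_id,
    gene_name = g$name, gene_biotype = g$biotype)
  gr_all <- gr_g
  if (nrow(tx) > 0) {
    gi <- match(tx$gene_id, g$gene_id)
    gr_t <- GenomicRanges::GRanges(
      tx$chrom, IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
      type = "transcript", source = "genemotif", gene_id = tx$gene_id,
      gene_name = g$name[gi], gene_biotype = g$biotype[gi],
      transcript_id = tx$transcript_id)
    gr_g$transcript_id <- NA_character_
    gr_all <- c(gr_g, gr_t)
  }
  rtracklayer::export(gr_all, file.path(outdir, "genes.gtf"),
                      format = "gtf")
  write_mutations(cohort$mutations, file.path(outdir, "mutations.tsv"))
  utils::write.table(cohort$clinical, file.path(outdir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subtype = as.list(cohort$truth$subtype),
         supercluster = as.list(cohort$truth$supercluster),
         enriched = cohort$truth$enriched,
         supercluster_enriched = cohort$truth$supercluster_enriched,
         driver_pool = cohort$truth$driver_pool),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
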