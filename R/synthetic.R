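#' Configuration for the synthetic expression generator
#'
#' Describes a two-class (case/control) log2 expression matrix with planted
#' structure: class-discriminative ("informative") features, redundant
#' noisy copies of informative features, planted lncRNA-mRNA co-expressed
#' pairs, and pure-noise features. Defaults emulate the study design the
#' pipeline was built for: 15 cases vs 15 controls on a two-biotype array,
#' at a desk scale of 2,000 features.
#'
#' @param n_case,n_control Samples per group (each >= 2, together >= 4).
#' @param n_informative Features whose group means differ by `effect_size`.
#' @param n_redundant Noisy copies of informative features (requires
#'   `n_informative >= 1` when positive); copies correlate > 0.95 with
#'   their source.
#' @param n_noise Features with identical distributions in both groups.
#' @param n_coexpressed Planted lncRNA-mRNA co-expressed pairs, carved out
#'   of the noise block (so `2 * n_coexpressed <= n_noise`); pair members
#'   share a latent factor and carry no class signal.
#' @param n_lnc_fraction Fraction of features tagged `lncRNA` (pair members
#'   are forced to straddle the two biotypes).
#' @param effect_size Between-group mean shift of informative features, in
#'   log2 units; alternating sign (odd-indexed up in cases, even down).
#' @param within_correlation Target Pearson r of planted pairs, in [0, 1].
#' @param noise_sd Within-group standard deviation, log2 units (> 0).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_case = 15L, n_control = 15L,
                             n_informative = 20L, n_redundant = 10L,
                             n_noise = 1970L, n_coexpressed = 10L,
                             n_lnc_fraction = 0.5, effect_size = 2,
                             within_correlation = 0.9, noise_sd = 1,
                             seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_informative = as.integer(n_informative),
              n_redundant = as.integer(n_redundant),
              n_noise = as.integer(n_noise),
              n_coexpressed = as.integer(n_coexpressed),
              n_lnc_fraction = n_lnc_fraction, effect_size = effect_size,
              within_correlation = within_correlation, noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_case < 2L || n_control < 2L || n_case + n_control < 4L)
      stop("need >= 2 samples per group (correlation degenerate otherwise)")
    if (n_informative < 0L || n_redundant < 0L || n_noise < 0L ||
        n_coexpressed < 0L)
      stop("feature counts must be >= 0")
    if (n_redundant > 0L && n_informative < 1L)
      stop("redundant copies need at least one informative source")
    if (2L * n_coexpressed > n_noise)
      stop("co-expressed pairs must fit inside the noise block")
    if (effect_size < 0) stop("'effect_size' must be >= 0")
    if (within_correlation < 0 || within_correlation > 1)
      stop("'within_correlation' must be in [0, 1]")
    if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic case/control expression matrix with ground truth
#'
#' Draws a log2-scale Gaussian expression matrix according to a
#' [synthetic_config()]. Per-feature baselines are N(8, 1.5) log2 units;
#' within-group noise is N(0, `noise_sd`). Informative features shift the
#' case-group mean by `effect_size` with alternating sign; redundant
#' features are an informative source plus N(0, `0.2 * noise_sd`)
#' perturbation (sample correlation with the source > 0.95); co-expressed
#' pairs mix a shared standard-normal latent factor with weight
#' `sqrt(within_correlation)` so the pair's population correlation equals
#' `within_correlation`. Feature ids are `LNC_####` / `MRNA_####` with
#' biotypes assigned at `n_lnc_fraction`, except that each planted pair is
#' forced to contain one lncRNA and one mRNA.
#'
#' @param config A [synthetic_config()].
#' @return List with `matrix` (an [expr_matrix]), `labels`
#'   ([class_labels()]), and `ground_truth`: list with `informative_ids`,
#'   `redundant_pairs` (data.frame source_id/copy_id) and
#'   `coexpressed_pairs` (data.frame lnc_id/mrna_id/planted_r).
#' @examples
#' sim <- generate_expression(synthetic_config(n_noise = 100, seed = 42))
#' sim$matrix
#' head(sim$ground_truth$informative_ids)
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  c2 <- config
  withr::with_seed(c2$seed, {
    n_feat <- c2$n_informative + c2$n_redundant + c2$n_noise
    if (n_feat < 1L) stop("no features requested")
    n_samp <- c2$n_case + c2$n_control
    grp <- rep(c("case", "control"), c(c2$n_case, c2$n_control))
    sample_ids <- sprintf("S%02d", seq_len(n_samp))

    # biotype assignment; planted pairs later straddle the partition
    n_lnc <- round(c2$n_lnc_fraction * n_feat)
    biotype <- rep("mRNA", n_feat)
    if (n_lnc > 0) biotype[sample.int(n_feat, n_lnc)] <- "lncRNA"

    idx_inf <- seq_len(c2$n_informative)
    idx_red <- c2$n_informative + seq_len(c2$n_redundant)
    idx_noise <- c2$n_informative + c2$n_redundant + seq_len(c2$n_noise)

    baseline <- stats::rnorm(n_feat, mean = 8, sd = 1.5)
    v <- matrix(stats::rnorm(n_feat * n_samp, sd = c2$noise_sd),
                n_feat, n_samp) + baseline

    # class signal: alternating direction so both up and down exist
    if (c2$n_informative > 0 && c2$effect_size > 0) {
      sign_i <- rep_len(c(1, -1), c2$n_informative)
      v[idx_inf, grp == "case"] <- v[idx_inf, grp == "case"] +
        sign_i * c2$effect_size
    }

    # redundant features: noisy copies of cycled informative sources
    src <- integer(0L)
    if (c2$n_redundant > 0L) {
      src <- rep_len(idx_inf, c2$n_redundant)
      v[idx_red, ] <- v[src, , drop = FALSE] +
        matrix(stats::rnorm(c2$n_redundant * n_samp, sd = 0.2 * c2$noise_sd),
               c2$n_redundant, n_samp)
    }

    # co-expressed pairs: first 2*n_coexpressed noise features, shared
    # latent factor z with mixing sqrt(rho) => corr(pair) = rho
    pair_a <- pair_b <- integer(0L)
    if (c2$n_coexpressed > 0L) {
      pair_a <- idx_noise[seq_len(c2$n_coexpressed) * 2L - 1L]
      pair_b <- idx_noise[seq_len(c2$n_coexpressed) * 2L]
      rho <- c2$within_correlation
      for (p in seq_len(c2$n_coexpressed)) {
        z <- stats::rnorm(n_samp)
        for (i in c(pair_a[p], pair_b[p])) {
          e <- stats::rnorm(n_samp)
          v[i, ] <- baseline[i] +
            c2$noise_sd * (sqrt(rho) * z + sqrt(1 - rho) * e)
        }
      }
      biotype[pair_a] <- "lncRNA"
      biotype[pair_b] <- "mRNA"
    }

    ids <- ifelse(biotype == "lncRNA",
                  sprintf("LNC_%04d", cumsum(biotype == "lncRNA")),
                  sprintf("MRNA_%04d", cumsum(biotype == "mRNA")))
    dimnames(v) <- list(ids, sample_ids)

    gt <- list(
      informative_ids = ids[idx_inf],
      redundant_pairs = data.frame(source_id = ids[src],
                                   copy_id = ids[idx_red]),
      coexpressed_pairs = data.frame(lnc_id = ids[pair_a],
                                     mrna_id = ids[pair_b],
                                     planted_r = rep(c2$within_correlation,
                                                     length(pair_a))))
    list(matrix = expr_matrix(v, stats::setNames(biotype, ids)),
         labels = class_labels(sample_ids, grp),
         ground_truth = gt)
  })
}

#' Generate a synthetic annotation collection with planted enrichment
#'
#' Builds `n_categories` gene sets over the features of a matrix. A
#' fraction of them ("planted-enriched") draw most of their members from
#' the ground-truth informative set, so a downstream over-representation
#' test of the informative list should rank them first; the rest are
#' uniform draws from the universe.
#'
#' @param matrix An [expr_matrix] defining the universe (all feature ids).
#' @param ground_truth Ground-truth list from [generate_expression()]
#'   (only `informative_ids` is used). Required when
#'   `enriched_category_fraction > 0`.
#' @param n_categories Number of categories (>= 1).
#' @param enriched_category_fraction Fraction of categories planted as
#'   enriched, in [0, 1].
#' @param category_size Members per category (default 20; capped at the
#'   universe size).
#' @param enriched_overlap Fraction of a planted category drawn from the
#'   informative set (default 0.8, capped by its size).
#' @param seed Integer seed.
#' @return List with `annotations` (an [annotation_collection]) and
#'   `enriched_ids` (character vector of planted category ids).
#' @export
generate_annotations <- function(matrix, ground_truth = NULL,
                                 n_categories = 50L,
                                 enriched_category_fraction = 0.1,
                                 category_size = 20L,
                                 enriched_overlap = 0.8, seed = 1L) {
  stopifnot(inherits(matrix, "expr_matrix"), n_categories >= 1L,
            enriched_category_fraction >= 0,
            enriched_category_fraction <= 1)
  universe <- features(matrix)
  if (category_size > length(universe))
    stop("category size must not exceed the universe size")
  n_enr <- round(enriched_category_fraction * n_categories)
  if (n_enr > 0L && is.null(ground_truth))
    stop("planted enrichment needs 'ground_truth'")
  withr::with_seed(seed, {
    cats <- vector("list", n_categories)
    for (i in seq_len(n_categories)) {
      if (i <= n_enr) {
        inf <- intersect(ground_truth$informative_ids, universe)
        n_from_inf <- min(length(inf),
                          max(1L, round(enriched_overlap * category_size)))
        members <- c(sample(inf, n_from_inf),
                     sample(setdiff(universe, inf),
                            category_size - n_from_inf))
      } else {
        members <- sample(universe, category_size)
      }
      cats[[i]] <- members
    }
    ids <- sprintf("CAT_%03d", seq_len(n_categories))
    names(cats) <- ids
    desc <- ifelse(seq_len(n_categories) <= n_enr,
                   "planted enriched category", "random category")
    list(annotations = annotation_collection(
           cats, stats::setNames(desc, ids), universe = universe),
         enriched_ids = ids[seq_len(n_enr)])
  })
}

#' Generate a synthetic qPCR Ct table with planted fold changes
#'
#' Produces threshold-cycle (Ct) values for target genes and a reference
#' gene in a case/control design, such that relative quantification by
#' [ddct_fold_change()] recovers `planted_fold_changes` exactly when
#' `noise_sd = 0`. Control-group target delta-Ct values (target minus
#' reference) are drawn once per gene in 2..8 cycles; the case group's
#' delta-Ct is shifted by `-log2(fold)`; Gaussian measurement noise of
#' `noise_sd` cycles is added to every well.
#'
#' @param n_targets Number of target genes (lengths are recycled against
#'   `planted_fold_changes`).
#' @param n_samples_per_group Samples per group.
#' @param planted_fold_changes Positive linear fold changes (case vs
#'   control), one per target.
#' @param ref_ct Reference-gene mean Ct, in 10..35 cycles (default 18).
#' @param noise_sd Per-well Ct noise, cycles (default 0).
#' @param seed Integer seed.
#' @return A `ct_table`: list with `ct` (gene x sample matrix of cycles),
#'   `reference` (reference gene id), `labels`, and `planted` (named
#'   vector of planted folds).
#' @export
generate_ct_table <- function(n_targets = NULL, n_samples_per_group = 15L,
                              planted_fold_changes = 2,
                              ref_ct = 18, noise_sd = 0, seed = 1L) {
  if (is.null(n_targets)) n_targets <- length(planted_fold_changes)
  stopifnot(n_targets >= 1L, n_samples_per_group >= 1L, noise_sd >= 0)
  if (any(planted_fold_changes <= 0))
    stop("planted fold changes must be > 0")
  if (ref_ct < 10 || ref_ct > 35)
    stop("'ref_ct' must be a plausible cycle number in [10, 35]")
  folds <- rep_len(planted_fold_changes, n_targets)
  withr::with_seed(seed, {
    n_samp <- 2L * n_samples_per_group
    grp <- rep(c("case", "control"), each = n_samples_per_group)
    sample_ids <- sprintf("S%02d", seq_len(n_samp))
    genes <- sprintf("GENE_%02d", seq_len(n_targets))
    base_dct <- stats::runif(n_targets, 2, 8)  # control-group delta-Ct
    ref_row <- ref_ct + stats::rnorm(n_samp, sd = noise_sd)
    ct <- matrix(0, n_targets + 1L, n_samp,
                 dimnames = list(c(genes, "REF"), sample_ids))
    ct["REF", ] <- ref_row
    for (g in seq_len(n_targets)) {
      dct <- ifelse(grp == "case", base_dct[g] - log2(folds[g]), base_dct[g])
      ct[genes[g], ] <- ref_ct + dct + stats::rnorm(n_samp, sd = noise_sd)
    }
    structure(list(ct = ct, reference = "REF",
                   labels = class_labels(sample_ids, grp),
                   planted = stats::setNames(folds, genes)),
              class = "ct_table")
  })
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d target gene(s) + reference '%s', %d samples\n",
              nrow(x$ct) - 1L, x$reference, ncol(x$ct)))
  invisible(x)
}

#' Write the ground-truth sidecar of a synthetic data set as JSON
#'
#' @param ground_truth The `ground_truth` list from [generate_expression()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
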