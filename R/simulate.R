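#' Configuration for the synthetic compendium generator
#'
#' Builds the parameter object consumed by [simulate_compendium()]. The
#' defaults emulate the structure of the Medicago truncatula Gene
#' Expression Atlas as used for nodule-specificity mining: 267
#' conditions spanning ten tissue classes, a nodule time course at
#' 0/3/4/6/10/14/28 dpi, five hand-dissected zone samples, five
#' laser-capture cell-type samples, senescence-induction contrasts, a
#' planted nodule-specific gene family activated in three temporal
#' waves, a handful of family genes with relaxed specificity, linear
#' hybridization signals with background near 9 and peaks up to 33,500,
#' and one cross-contaminated mycorrhiza sample.
#'
#' @param n_genes Total number of genes (default 500).
#' @param n_family Size of the planted nodule-specific family
#'   (default 60); the relaxed genes are members of this family.
#' @param n_relaxed Number of family genes given reproducible expression
#'   in root and stem conditions (default 5).
#' @param n_senescence_markers Non-family genes strongly induced by the
#'   senescence treatments (default 8).
#' @param n_bacterial_markers Genes tracking bacterial RNA, expressed
#'   only in infected nodule tissue (default 10); used for
#'   contamination QC.
#' @param n_uc_specific Family genes expressed higher in uninfected than
#'   infected cells (default 2, with fold excesses `uc_folds`).
#' @param uc_folds UC/IC fold excess for the UC-specific genes
#'   (default `c(9.6, 3.2)`).
#' @param tissue_panel Data frame `organ`/`reps` for the simple
#'   whole-organ tissues (leaf, petiole, stem, bud, flower, pod,
#'   mycorrhiza by default, 3 replicates each).
#' @param nodule_timepoints Nodule time course in days post inoculation;
#'   0 dpi is the uninoculated root control and is generated as a root
#'   condition (default `c(0, 3, 4, 6, 10, 14, 28)`).
#' @param nodule_reps Replicates per nodule timepoint (default 6; the
#'   source atlas holds 42 nodule samples across the course).
#' @param seed_timepoints Seed development course in days after
#'   pollination (default `c(10, 12, 16, 20, 24, 36)`, 2 reps each).
#' @param zone_samples,lcm_samples Logical; include the hand-dissected
#'   zone samples (I, II, II-III, III, IV) and the LCM cell-type
#'   samples (M, dIZ, pIZ, IC, UC).
#' @param zone_reps,lcm_reps Replicates per zone / cell-type sample.
#' @param senescence_contrast Logical; include control plus nitrate- and
#'   herbicide-treated senescent nodule samples (3 reps each).
#' @param n_extra_conditions Filler treatment conditions (stress and
#'   hormone series on vegetative organs) padding the compendium to the
#'   atlas-like total of 267 (default 150).
#' @param wave_fractions Proportions of family genes in waves 1, 2 and 3
#'   (must sum to 1; default equal thirds).
#' @param declining_fraction Fraction of family genes per wave whose
#'   expression declines in the oldest nodules (default 1/3).
#' @param background_mean Median background signal (default 9).
#' @param peak_signal_range Range of family nodule peak levels, drawn
#'   log-uniformly (default 5,000 to 33,500).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (default 0.2).
#' @param senescence_down_factor Multiplier on family expression under
#'   senescence induction (default 0.2).
#' @param marker_up_factor Multiplier on senescence-marker expression
#'   under senescence induction (default 5).
#' @param organ_specific_fraction Fraction of ordinary genes given
#'   single-organ specific expression outside the nodule, so that
#'   low-entropy non-family genes exist (default 0.06).
#' @param contamination `NULL` for none, or a list with `target`
#'   (condition id, default the first mycorrhiza sample), `donor`
#'   (default the first 14 dpi nodule sample) and `proportion` in (0,1)
#'   (default 0.2): the target column becomes
#'   `(1 - p) * target + p * donor`.
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 500L,
                             n_family = 60L,
                             n_relaxed = 5L,
                             n_senescence_markers = 8L,
                             n_bacterial_markers = 10L,
                             n_uc_specific = 2L,
                             uc_folds = c(9.6, 3.2),
                             tissue_panel = data.frame(
                               organ = c("leaf", "petiole", "stem", "bud",
                                         "flower", "pod", "mycorrhiza"),
                               reps = 3L),
                             nodule_timepoints = c(0, 3, 4, 6, 10, 14, 28),
                             nodule_reps = 6L,
                             seed_timepoints = c(10, 12, 16, 20, 24, 36),
                             zone_samples = TRUE, zone_reps = 3L,
                             lcm_samples = TRUE, lcm_reps = 3L,
                             senescence_contrast = TRUE,
                             n_extra_conditions = 150L,
                             wave_fractions = c(1, 1, 1) / 3,
                             declining_fraction = 1 / 3,
                             background_mean = 9,
                             peak_signal_range = c(5000, 33500),
                             noise_cv = 0.2,
                             senescence_down_factor = 0.2,
                             marker_up_factor = 5,
                             organ_specific_fraction = 0.06,
                             contamination = list(target = NULL, donor = NULL,
                                                  proportion = 0.2),
                             seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synthetic_config")
  if (cfg$n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (cfg$n_family < 0L || cfg$n_family > cfg$n_genes)
    stop("n_family must be in [0, n_genes]", call. = FALSE)
  if (cfg$n_relaxed < 0L || cfg$n_relaxed > cfg$n_family)
    stop("n_relaxed must be in [0, n_family]", call. = FALSE)
  if (cfg$n_uc_specific > cfg$n_family - cfg$n_relaxed)
    stop("n_uc_specific exceeds available family genes", call. = FALSE)
  if (length(cfg$uc_folds) < cfg$n_uc_specific)
    stop("uc_folds must supply one fold per UC-specific gene", call. = FALSE)
  if (cfg$n_family + cfg$n_senescence_markers + cfg$n_bacterial_markers >
      cfg$n_genes)
    stop("family plus marker genes exceed n_genes", call. = FALSE)
  if (abs(sum(cfg$wave_fractions) - 1) > 1e-9)
    stop("wave_fractions must sum to 1", call. = FALSE)
  if (!is.null(cfg$contamination)) {
    p <- cfg$contamination$proportion
    if (!is.numeric(p) || p <= 0 || p >= 1)
      stop("contamination proportion must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (cfg$background_mean <= 0)
    stop("background_mean must be positive", call. = FALSE)
  if (diff(cfg$peak_signal_range) < 0 || cfg$peak_signal_range[1L] <= 0)
    stop("peak_signal_range must be increasing and positive", call. = FALSE)
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "synthetic_config: %d genes (%d family, %d relaxed), noise cv %.2f, seed %s\n",
    x$n_genes, x$n_family, x$n_relaxed, x$noise_cv, format(x$seed)))
  invisible(x)
}

# Condition layout implied by a config. Internal; the metadata it returns
# is the ground plan onto which signals are drawn.
build_condition_table <- function(cfg) {
  rows <- list()
  add <- function(id, organ, treatment = "none", timepoint = NA_real_,
                  unit = NA_character_, cls = "whole_organ", group) {
    rows[[length(rows) + 1L]] <<- data.frame(
      condition_id = id, organ = organ, treatment = treatment,
      timepoint = timepoint, timepoint_unit = unit, sample_class = cls,
      replicate_group = group, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(cfg$tissue_panel))) {
    org <- cfg$tissue_panel$organ[i]
    for (r in seq_len(cfg$tissue_panel$reps[i]))
      add(sprintf("%s_%d", org, r), org, group = org)
  }
  # root: expA doubles as the 0 dpi nodulation control, expB independent
  has0 <- 0 %in% cfg$nodule_timepoints
  n0 <- if (has0) cfg$nodule_reps else 3L
  for (r in seq_len(n0))
    add(sprintf("root_expA_%d", r), "root",
        timepoint = if (has0) 0 else NA_real_,
        unit = if (has0) "dpi" else NA_character_, group = "root_expA")
  for (r in 1:3)
    add(sprintf("root_expB_%d", r), "root", group = "root_expB")
  for (t in setdiff(cfg$nodule_timepoints, 0))
    for (r in seq_len(cfg$nodule_reps))
      add(sprintf("nod_%gdpi_%d", t, r), "nodule", timepoint = t,
          unit = "dpi", group = sprintf("nod_%gdpi", t))
  for (t in cfg$seed_timepoints)
    for (r in 1:2)
      add(sprintf("seed_%gdap_%d", t, r), "seed", timepoint = t,
          unit = "dap", group = sprintf("seed_%gdap", t))
  if (isTRUE(cfg$zone_samples)) {
    zones <- c("zone_I", "zone_II", "zone_II_III", "zone_III", "zone_IV")
    for (z in zones)
      for (r in seq_len(cfg$zone_reps))
        add(sprintf("%s_%d", z, r), "nodule", timepoint = 28, unit = "dpi",
            cls = z, group = z)
  }
  if (isTRUE(cfg$lcm_samples)) {
    lcm <- c("lcm_M", "lcm_dIZ", "lcm_pIZ", "lcm_IC", "lcm_UC")
    for (z in lcm)
      for (r in seq_len(cfg$lcm_reps))
        add(sprintf("%s_%d", z, r), "nodule", cls = z, group = z)
  }
  if (isTRUE(cfg$senescence_contrast)) {
    for (r in 1:3)
      add(sprintf("sen_control_%d", r), "nodule",
          treatment = "senescence_control", timepoint = 28, unit = "dpi",
          group = "sen_control")
    for (trt in c("nitrate", "phosphinothricin"))
      for (r in 1:3)
        add(sprintf("sen_%s_%d", trt, r), "nodule", treatment = trt,
            timepoint = 28, unit = "dpi", group = sprintf("sen_%s", trt))
  }
  if (cfg$n_extra_conditions > 0L) {
    organs <- c("root", "leaf", "stem", "flower")
    trts <- c("salt", "drought", "cold", "heat", "auxin", "cytokinin",
              "pathogen", "wounding", "ABA", "nematode")
    for (k in seq_len(cfg$n_extra_conditions)) {
      org <- organs[(k - 1L) %% length(organs) + 1L]
      trt <- trts[((k - 1L) %/% length(organs)) %% length(trts) + 1L]
      add(sprintf("x_%s_%s_%d", org, trt, k), org, treatment = trt,
          group = sprintf("x_%s_%s", org, trt))
    }
  }
  do.call(rbind, rows)
}

# Logistic activation rescaled to be exactly 0 at 3 dpi (no family
# expression before infected cells form) and to approach 1 at maturity.
.WAVE_MID <- c(3.2, 5.2, 7.5)
.WAVE_SCALE <- c(0.5, 0.6, 0.5)

wave_activation <- function(t, wave) {
  m <- .WAVE_MID[wave]; s <- .WAVE_SCALE[wave]
  p3 <- stats::plogis((3 - m) / s)
  pmax(0, (stats::plogis((t - m) / s) - p3) / (1 - p3))
}

# wave x zone relative levels; rows waves 1..3, columns I..IV.
.ZONE_W <- rbind(c(0.80, 1.00, 0.60, 0.30, 0.15),
                 c(0.20, 0.80, 1.00, 0.80, 0.30),
                 c(0.05, 0.30, 0.80, 1.00, 0.50))
# wave x LCM cell type; columns M, dIZ, pIZ, IC, UC. Meristem is free of
# rhizobia, uninfected cells carry only trace signal.
.LCM_W <- rbind(c(0.02, 1.00, 0.80, 0.60, 0.05),
                c(0.02, 0.50, 1.00, 0.80, 0.05),
                c(0.02, 0.10, 0.50, 1.00, 0.05))
.BAC_ZONE_W <- c(0.05, 0.80, 1.00, 1.00, 0.80)
.BAC_LCM_W <- c(0.02, 0.80, 1.00, 1.00, 0.30)

#' Simulate a compendium with planted ground truth
#'
#' Draws a gene x condition signal matrix according to a
#' [synthetic_config()] and returns it together with the planted truth
#' labels, so that entropy ranking, wave assignment, zone profiling,
#' differential screens and contamination QC can all be validated by
#' recovery. Deterministic given the config (same config, same matrix).
#'
#' Structure planted (see [synthetic_config()] for the knobs):
#' ordinary genes carry organ-specific baselines under multiplicative
#' log-normal noise; a minority are organ-specific outside the nodule.
#' Family genes sit at probe-specific background everywhere except
#' nodule tissue, where they activate along one of three logistic waves
#' (full level by roughly 4, 6-10 and 10-14 dpi) with matching
#' apical-to-proximal zone profiles; senescence induction multiplies
#' them down and the senescence markers up; relaxed genes additionally
#' express in root and stem; bacterial markers follow infected tissue
#' only; one optional condition is a target/donor signal mixture.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `compendium` (a [compendium()]), `truth`
#'   (list of data frames `genes` and `conditions` with the planted
#'   labels) and `annotation` (gene annotation table as read by
#'   [read_annotation()]).
#' @examples
#' sim <- simulate_compendium(synthetic_config(n_genes = 100, n_family = 12,
#'                                             n_extra_conditions = 10,
#'                                             seed = 42))
#' sim$compendium
#' table(sim$truth$genes$wave, useNA = "ifany")
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))

  meta <- build_condition_table(cfg)
  n_cond <- nrow(meta)
  gene_id <- sprintf("g%04d", seq_len(cfg$n_genes))

  # --- roles ---------------------------------------------------------
  idx <- sample.int(cfg$n_genes)          # scatter roles over gene ids
  fam_idx <- sort(idx[seq_len(cfg$n_family)])
  rest <- idx[-seq_len(cfg$n_family)]
  sen_idx <- sort(rest[seq_len(cfg$n_senescence_markers)])
  rest <- rest[-seq_len(cfg$n_senescence_markers)]
  bac_idx <- if (cfg$n_bacterial_markers > 0L)
    sort(rest[seq_len(cfg$n_bacterial_markers)]) else integer(0)
  ordinary_idx <- sort(setdiff(seq_len(cfg$n_genes),
                               c(fam_idx, sen_idx, bac_idx)))

  relaxed_idx <- if (cfg$n_relaxed > 0L)
    sort(sample(fam_idx, cfg$n_relaxed)) else integer(0)
  uc_idx <- if (cfg$n_uc_specific > 0L)
    sort(sample(setdiff(fam_idx, relaxed_idx), cfg$n_uc_specific))
  else integer(0)

  wave <- rep(NA_integer_, cfg$n_genes)
  if (cfg$n_family > 0L) {
    n_w <- floor(cfg$wave_fractions * cfg$n_family)
    while (sum(n_w) < cfg$n_family)
      n_w[which.max(cfg$wave_fractions * cfg$n_family - n_w)] <-
        n_w[which.max(cfg$wave_fractions * cfg$n_family - n_w)] + 1L
    wave[fam_idx] <- sample(rep(1:3, times = n_w))
  }
  declining <- rep(FALSE, cfg$n_genes)
  if (cfg$n_family > 0L && cfg$declining_fraction > 0)
    declining[fam_idx] <- stats::runif(cfg$n_family) < cfg$declining_fraction

  n_spec <- round(cfg$organ_specific_fraction * length(ordinary_idx))
  spec_idx <- if (n_spec > 0L) sort(sample(ordinary_idx, n_spec)) else integer(0)
  spec_organ <- rep(NA_character_, cfg$n_genes)
  if (n_spec > 0L)
    spec_organ[spec_idx] <- sample(c("seed", "flower", "root", "leaf", "pod"),
                                   n_spec, replace = TRUE)

  # --- per-gene levels ----------------------------------------------
  bg <- cfg$background_mean
  # probe-affinity background: shared across conditions, so that two
  # pre-activation timepoints correlate as they do on real arrays
  fam_bg <- pmin(stats::rlnorm(cfg$n_genes, log(bg), 1.0), 10 * bg)
  peak <- exp(stats::runif(cfg$n_genes, log(cfg$peak_signal_range[1L]),
                           log(cfg$peak_signal_range[2L])))
  relaxed_level <- exp(stats::runif(cfg$n_genes, log(600), log(3000)))
  uc_fold <- rep(NA_real_, cfg$n_genes)
  if (length(uc_idx)) uc_fold[uc_idx] <- cfg$uc_folds[seq_along(uc_idx)]

  base_level <- exp(stats::rnorm(cfg$n_genes, log(100), 1.5))
  base_level <- pmin(base_level, 20000)
  organ_names <- .ORGANS
  organ_factor <- matrix(exp(stats::rnorm(cfg$n_genes * length(organ_names),
                                          0, 0.4)),
                         nrow = cfg$n_genes,
                         dimnames = list(gene_id, organ_names))
  spec_level <- exp(stats::rnorm(cfg$n_genes, log(2000), 0.7))
  spec_base <- pmin(stats::rlnorm(cfg$n_genes, log(20), 0.8), 300)
  bac_level <- exp(stats::runif(cfg$n_genes, log(2000), log(8000)))

  is_fam <- seq_len(cfg$n_genes) %in% fam_idx
  is_sen <- seq_len(cfg$n_genes) %in% sen_idx
  is_bac <- seq_len(cfg$n_genes) %in% bac_idx
  is_spec <- seq_len(cfg$n_genes) %in% spec_idx
  is_relaxed <- seq_len(cfg$n_genes) %in% relaxed_idx
  is_uc <- seq_len(cfg$n_genes) %in% uc_idx

  decay28 <- function(t) 1 - 0.7 * pmax(0, (t - 14) / 14)  # decline in old nodules

  # --- expected (noise-free) signal per gene x condition -------------
  mu <- matrix(bg, nrow = cfg$n_genes, ncol = n_cond,
               dimnames = list(gene_id, meta$condition_id))
  zone_cols <- c("zone_I", "zone_II", "zone_II_III", "zone_III", "zone_IV")
  lcm_cols <- c("lcm_M", "lcm_dIZ", "lcm_pIZ", "lcm_IC", "lcm_UC")

  for (j in seq_len(n_cond)) {
    org <- meta$organ[j]; cls <- meta$sample_class[j]
    trt <- meta$treatment[j]; tp <- meta$timepoint[j]
    unit <- meta$timepoint_unit[j]
    is_nodule_tp <- org == "nodule" & cls == "whole_organ" &
      !is.na(tp) & identical(unit, "dpi") & trt == "none"
    sen_cond <- trt %in% c("senescence_control", "nitrate", "phosphinothricin")

    # ordinary genes (incl. senescence/bacterial baseline behaviour)
    v <- base_level * organ_factor[, org]
    v[is_spec] <- ifelse(spec_organ[is_spec] == org,
                         spec_level[is_spec], spec_base[is_spec])
    v[is_bac] <- fam_bg[is_bac]
    v[is_fam] <- fam_bg[is_fam]
    mu[, j] <- v

    if (is_nodule_tp) {
      act <- wave_activation(tp, wave[is_fam])
      mu[is_fam, j] <- fam_bg[is_fam] + peak[is_fam] * act *
        ifelse(declining[is_fam], decay28(tp), 1)
      mu[is_bac, j] <- fam_bg[is_bac] +
        bac_level[is_bac] * wave_activation(tp, 2L)
    } else if (cls %in% zone_cols) {
      zi <- match(cls, zone_cols)
      mu[is_fam, j] <- fam_bg[is_fam] +
        peak[is_fam] * .ZONE_W[cbind(wave[is_fam], zi)]
      mu[is_bac, j] <- fam_bg[is_bac] + bac_level[is_bac] * .BAC_ZONE_W[zi]
    } else if (cls %in% lcm_cols) {
      li <- match(cls, lcm_cols)
      w <- .LCM_W[cbind(wave[is_fam], li)]
      mu[is_fam, j] <- fam_bg[is_fam] + peak[is_fam] * w
      if (cls == "lcm_UC" && any(is_uc)) {
        ic <- .LCM_W[cbind(wave[is_uc], match("lcm_IC", lcm_cols))]
        mu[is_uc, j] <- fam_bg[is_uc] + peak[is_uc] * ic * uc_fold[is_uc]
      }
      mu[is_bac, j] <- fam_bg[is_bac] + bac_level[is_bac] * .BAC_LCM_W[li]
    } else if (sen_cond) {
      down <- if (trt == "senescence_control") 1 else cfg$senescence_down_factor
      up <- if (trt == "senescence_control") 1 else cfg$marker_up_factor
      mu[is_fam, j] <- fam_bg[is_fam] + peak[is_fam] * down
      mu[is_sen, j] <- mu[is_sen, j] * up
      mu[is_bac, j] <- fam_bg[is_bac] +
        bac_level[is_bac] * (if (trt == "senescence_control") 1 else 0.5)
    }
    # relaxed family genes: reproducible expression in root and stem;
    # early nodule primordia (<= 3 dpi) are still mostly root tissue
    if (any(is_relaxed) &&
        (org %in% c("root", "stem") ||
         (is_nodule_tp && tp <= 3)))
      mu[is_relaxed, j] <- fam_bg[is_relaxed] + relaxed_level[is_relaxed]
  }

  # hybridization floor: linear-scale signals never drop below background
  mu <- pmax(mu, bg)

  # --- multiplicative log-normal noise, unit mean --------------------
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- matrix(stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog),
                    nrow = nrow(mu))
    sig <- mu * noise
  } else sig <- mu

  # --- contamination -------------------------------------------------
  contaminated <- rep(FALSE, n_cond)
  mixing <- rep(NA_real_, n_cond)
  if (!is.null(cfg$contamination)) {
    target <- cfg$contamination$target
    if (is.null(target)) {
      myco <- meta$condition_id[meta$organ == "mycorrhiza"]
      if (!length(myco)) stop("no mycorrhiza condition to contaminate",
                              call. = FALSE)
      target <- myco[1L]
    }
    donor <- cfg$contamination$donor
    if (is.null(donor)) {
      nod <- meta$condition_id[meta$organ == "nodule" &
                                 meta$sample_class == "whole_organ" &
                                 meta$treatment == "none" &
                                 !is.na(meta$timepoint) & meta$timepoint == 14]
      if (!length(nod))
        nod <- meta$condition_id[meta$organ == "nodule"]
      donor <- nod[1L]
    }
    p <- cfg$contamination$proportion
    sig[, target] <- (1 - p) * sig[, target] + p * sig[, donor]
    contaminated[match(target, meta$condition_id)] <- TRUE
    mixing[match(target, meta$condition_id)] <- p
  }

  family <- rep("other", cfg$n_genes)
  family[is_fam] <- "NCR"
  family[is_sen] <- "senescence_marker"
  family[is_bac] <- "bacterial_marker"

  truth_genes <- data.frame(
    gene_id = gene_id, family = family, is_family = is_fam,
    wave = wave, relaxed = is_relaxed, senescence_marker = is_sen,
    bacterial_marker = is_bac, uc_specific = is_uc, uc_fold = uc_fold,
    declining = declining & is_fam, organ_specific = spec_organ,
    stringsAsFactors = FALSE)
  truth_cond <- data.frame(
    condition_id = meta$condition_id, contaminated = contaminated,
    mixing = mixing, stringsAsFactors = FALSE)
  annotation <- data.frame(
    gene_id = gene_id, family = family,
    label = ifelse(is_fam, "planted family gene",
                   ifelse(is_sen, "senescence marker",
                          ifelse(is_bac, "bacterial marker", "ordinary"))),
    stringsAsFactors = FALSE)

  list(compendium = compendium(sig, meta),
       truth = list(genes = truth_genes, conditions = truth_cond),
       annotation = annotation)
}

#' Write the planted truth labels as TSV files
#'
#' @param truth The `truth` element of a [simulate_compendium()] result.
#' @param genes_path,conditions_path Output paths.
#' @return `genes_path`, invisibly.
#' @export
write_truth <- function(truth, genes_path, conditions_path) {
  write_table(truth$genes, genes_path)
  write_table(truth$conditions, conditions_path)
  invisible(genes_path)
}
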