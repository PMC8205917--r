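#' Planted-marker specification
#'
#' Describes one discriminative miRNA planted in a synthetic cohort:
#' `effect` is the case-minus-control shift in log2 units; `role`
#' documents its intent (`up`/`down`/`moderate`/`suppressor`);
#' `latent_loading` couples the miRNA to a shared per-sample nuisance
#' factor. A suppressor has (near-)zero marginal effect but a nonzero
#' loading shared with a true marker, so that a multivariate model can
#' use it to cancel correlated noise — the mechanism by which a miRNA
#' with chance-level marginal AUC still raises a panel's AUC.
#'
#' @param mirna_id character id.
#' @param effect case-minus-control shift, log2 units.
#' @param role one of `"up"`, `"down"`, `"moderate"`, `"suppressor"`.
#' @param latent_loading coupling to the shared nuisance factor.
#' @export
marker_spec <- function(mirna_id, effect,
                        role = c("up", "down", "moderate", "suppressor"),
                        latent_loading = 0) {
  role <- match.arg(role)
  ok <- switch(role,
    up = effect > 0, moderate = effect > 0, down = effect < 0,
    suppressor = abs(effect) < 0.1 && latent_loading != 0)
  if (!ok) abort(sprintf("effect/loading inconsistent with role '%s'", role))
  tibble::tibble(mirna_id = mirna_id, effect = effect, role = role,
                 latent_loading = latent_loading)
}

#' @rdname marker_spec
#' @details `default_markers()` plants four miRNAs: a strong up-marker
#'   (+1.6 log2), a down-marker (-1.2), a moderate up-marker (+0.8) and
#'   a suppressor (effect 0). The up-marker and the suppressor share the
#'   latent nuisance factor with loading 0.9 (marginal correlation
#'   0.81), so the suppressor's marginal AUC stays at chance level while
#'   the pair's joint discrimination — and hence the four-marker panel's
#'   accuracy and AUC — reaches the range reported for strong serum
#'   miRNA panels (theoretical panel accuracy/AUC about 0.94/0.985).
#' @export
default_markers <- function() {
  dplyr::bind_rows(
    marker_spec("miR-up-1", 1.6, "up", latent_loading = 0.9),
    marker_spec("miR-down-1", -1.2, "down"),
    marker_spec("miR-mod-1", 0.8, "moderate"),
    marker_spec("miR-supp-1", 0, "suppressor", latent_loading = 0.9))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a matched case-control serum microarray study:
#' 1417 cases and 1417 controls drawn from three control sources
#' (35.1/32.7/32.2%), lognormal signal intensities with a detection
#' floor, three stable internal-control miRNAs, per-sample multiplicative
#' technical factors that internal-control normalization must remove,
#' small per-source batch shifts, and the planted markers of
#' [default_markers()]. `mirna_log2_sd` is the *marginal* log2 sd of
#' every miRNA; markers with a latent loading get residual sd
#' `sqrt(mirna_log2_sd^2 - loading^2)` so the closed-form marginal AUC
#' `pnorm(effect / (sd * sqrt(2)))` holds for all of them.
#'
#' @param n_case,n_control cohort sizes.
#' @param control_source_fractions named proportions (A/B/C) summing to 1.
#' @param n_mirna number of miRNAs on the chip (300 keeps tests fast;
#'   2565 mimics a full chip).
#' @param control_mirna_ids exactly three internal-control ids.
#' @param baseline_log2_range uniform range of filler baselines (log2).
#' @param marker_baseline_log2 baseline of planted markers, safely above
#'   the robust-filter threshold.
#' @param mirna_log2_sd marginal per-miRNA log2 sd.
#' @param control_mirna_sd log2 sd of the internal controls.
#' @param detection_floor minimum raw signal before the technical factor.
#' @param planted_markers a tibble of [marker_spec()] rows (may be empty).
#' @param batch_shifts named per-control-source additive log2 offsets.
#' @param technical_sd log2 sd of the per-sample multiplicative factor.
#' @param stage_fractions,histology_fractions case proportions.
#' @param age_mean,age_sd,age_range age distribution (normal, truncated).
#' @param male_fraction proportion of males in both groups.
#' @param seed integer RNG seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_case = 1417, n_control = 1417,
                          control_source_fractions = c(A = 0.351, B = 0.327, C = 0.322),
                          n_mirna = 300,
                          control_mirna_ids = c("miR-ctrl-1", "miR-ctrl-2", "miR-ctrl-3"),
                          baseline_log2_range = c(2, 10),
                          marker_baseline_log2 = 8,
                          mirna_log2_sd = 1,
                          control_mirna_sd = 0.05,
                          detection_floor = 8,
                          planted_markers = default_markers(),
                          batch_shifts = c(A = -0.2, B = 0, C = 0.2),
                          technical_sd = 0.3,
                          stage_fractions = c(IA = 0.952, IB = 0.041, II = 0.007),
                          histology_fractions = c(differentiated = 0.564,
                                                  undifferentiated = 0.422,
                                                  special = 0.014),
                          age_mean = 65, age_sd = 11, age_range = c(20, 90),
                          male_fraction = 0.72,
                          seed = 1L) {
  check_fractions <- function(x, name) {
    if (any(x < 0 | x > 1) || abs(sum(x) - 1) > 1e-8) {
      abort(sprintf("`%s` must be proportions in [0,1] summing to 1", name))
    }
  }
  check_fractions(control_source_fractions, "control_source_fractions")
  check_fractions(stage_fractions, "stage_fractions")
  check_fractions(histology_fractions, "histology_fractions")
  if (length(control_mirna_ids) != 3L) abort("exactly 3 control miRNAs required")
  if (n_mirna <= nrow(planted_markers) + 3L) {
    abort("n_mirna must exceed the number of planted markers plus the 3 controls")
  }
  if (nrow(planted_markers) &&
      any(abs(planted_markers$latent_loading) >= mirna_log2_sd)) {
    abort("|latent_loading| must be below mirna_log2_sd")
  }
  cfg <- as.list(environment())
  cfg$check_fractions <- NULL
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic case-control serum miRNA cohort
#'
#' For each sample the log2 biological signal of miRNA `m` is
#' `baseline_m + effect_m * is_case + batch_shift(source) +
#' loading_m * Z_sample + noise`; the raw signal is `2^log2` clipped
#' below at the detection floor and then multiplied by a sample-wide
#' lognormal technical factor (which normalization to the internal
#' controls removes exactly). Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a list with `expression` (a raw-scale [mir_expr]) and
#'   `samples` (a [sample_table()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_case + config$n_control
  is_case <- rep(c(TRUE, FALSE), c(config$n_case, config$n_control))
  sample_id <- c(sprintf("EGC-%04d", seq_len(config$n_case)),
                 sprintf("CTL-%04d", seq_len(config$n_control)))

  src <- rep("none", n)
  src[!is_case] <- sample(names(config$control_source_fractions), config$n_control,
                          replace = TRUE, prob = config$control_source_fractions)
  stage <- rep("none", n)
  stage[is_case] <- sample(names(config$stage_fractions), config$n_case,
                           replace = TRUE, prob = config$stage_fractions)
  histology <- rep("none", n)
  histology[is_case] <- sample(names(config$histology_fractions), config$n_case,
                               replace = TRUE, prob = config$histology_fractions)
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  out_of_range <- age < config$age_range[1] | age > config$age_range[2]
  while (any(out_of_range)) {
    age[out_of_range] <- stats::rnorm(sum(out_of_range), config$age_mean, config$age_sd)
    out_of_range <- age < config$age_range[1] | age > config$age_range[2]
  }
  gender <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")

  samples <- sample_table(tibble::tibble(
    sample_id = sample_id,
    group = ifelse(is_case, "case", "control"),
    control_source = src, age = round(age), gender = gender,
    stage = stage, histology = histology, split = "unassigned"))

  mk <- config$planted_markers
  n_filler <- config$n_mirna - 3L - nrow(mk)
  mirna_id <- c(config$control_mirna_ids, mk$mirna_id,
                sprintf("miR-syn-%04d", seq_len(n_filler)))
  baseline <- c(rep(10, 3L), rep(config$marker_baseline_log2, nrow(mk)),
                stats::runif(n_filler, config$baseline_log2_range[1],
                             config$baseline_log2_range[2]))
  effect <- c(rep(0, 3L), mk$effect, rep(0, n_filler))
  loading <- c(rep(0, 3L), mk$latent_loading, rep(0, n_filler))
  resid_sd <- c(rep(config$control_mirna_sd, 3L),
                sqrt(config$mirna_log2_sd^2 - mk$latent_loading^2),
                rep(config$mirna_log2_sd, n_filler))

  shift <- rep(0, n)
  has_shift <- src %in% names(config$batch_shifts)
  shift[has_shift] <- config$batch_shifts[src[has_shift]]
  z <- stats::rnorm(n)

  p <- length(mirna_id)
  log2sig <- baseline + outer(effect, as.numeric(is_case)) +
    outer(loading, z) +
    matrix(shift, p, n, byrow = TRUE) +
    matrix(stats::rnorm(p * n), p, n) * resid_sd
  bio <- pmax(2^log2sig, config$detection_floor)
  tech <- 2^stats::rnorm(n, 0, config$technical_sd)
  raw <- sweep(bio, 2L, tech, `*`)
  dimnames(raw) <- list(mirna_id, sample_id)

  list(expression = mir_expr(raw, scale = "raw"), samples = samples)
}

#' Split a cohort into discovery and validation sets
#'
#' Stratified by group, and by control source within the controls.
#' Stratum allocations use largest-remainder rounding with seeded random
#' tie-breaks, so every stratum is within one sample of the exact ratio
#' and the arm totals equal `floor`/`ceiling` of `n * ratio` (1417 cases
#' + 1417 controls at 1:1 gives arms of 708 + 709 and 709 + 708).
#'
#' @param samples a [sample_table()].
#' @param ratio proportion assigned to the discovery arm, in (0, 1).
#' @param seed integer seed; the assignment is deterministic given it.
#' @return the sample table with `split` filled in.
#' @export
split_discovery_validation <- function(samples, ratio = 0.5, seed = 1L) {
  samples <- sample_table(samples)
  if (!(ratio > 0 && ratio < 1)) abort("ratio must be in (0, 1)")
  set.seed(seed)
  stratum <- paste(samples$group, samples$control_source, sep = "/")
  sizes <- table(stratum)
  quota <- as.numeric(sizes) * ratio
  base <- floor(quota)
  remainder <- quota - base
  total <- sum(quota)
  target <- floor(total) + stats::rbinom(1L, 1L, total - floor(total))
  extra_n <- target - sum(base)
  extra <- integer(length(base))
  if (extra_n > 0) {
    ord <- order(-remainder, stats::runif(length(remainder)))
    extra[ord[seq_len(extra_n)]] <- 1L
  }
  n_disc <- setNames(base + extra, names(sizes))

  samples$split <- "validation"
  for (s in names(sizes)) {
    rows <- which(stratum == s)
    pick <- sample(rows, n_disc[[s]])
    samples$split[pick] <- "discovery"
  }
  samples
}
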