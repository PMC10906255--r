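# Synthetic plasma LDI-MS cohorts with known differential metabolites.
# Signal model: each metabolite contributes one Gaussian peak per cation
# adduct; intensities are log-normal (multiplicative noise); planted group
# effects are standardized shifts on log intensity (Cohen's d units), so the
# realized additive log shift is effect * sdlog with sdlog = sqrt(log(1+cv^2)).

#' Instrument-noise specification for the spectrum simulator
#'
#' @param baseline_amplitude Baseline height at 100 Da (intensity units).
#' @param baseline_decay Exponential decay rate of the baseline (per Da).
#' @param mz_jitter_sd Per-peak m/z jitter standard deviation (Da).
#' @param intensity_cv Coefficient of variation of peak intensity
#'   (multiplicative log-normal noise), in `[0, 1)`.
#' @param additive_noise_sd Additive Gaussian noise sd (intensity units).
#' @param dropout_prob Probability that a peak is missing from a spectrum.
#' @param peak_width_sigma Gaussian peak sigma in Da (shape parameter,
#'   constant across the 100-400 Da window; must be positive).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amplitude = 50, baseline_decay = 0.01,
                       mz_jitter_sd = 0.02, intensity_cv = 0.15,
                       additive_noise_sd = 5, dropout_prob = 0.02,
                       peak_width_sigma = 0.08) {
  stopifnot(
    baseline_amplitude >= 0, baseline_decay >= 0, mz_jitter_sd >= 0,
    intensity_cv >= 0, intensity_cv < 1, additive_noise_sd >= 0,
    dropout_prob >= 0, dropout_prob < 1, peak_width_sigma > 0
  )
  structure(list(
    baseline_amplitude = baseline_amplitude, baseline_decay = baseline_decay,
    mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
    additive_noise_sd = additive_noise_sd, dropout_prob = dropout_prob,
    peak_width_sigma = peak_width_sigma
  ), class = "noise_spec")
}

#' Noise-free limit of [noise_spec()]
#'
#' Zero baseline, jitter, intensity variation, additive noise and dropout;
#' the Gaussian peak width is kept (a shape, not a noise, parameter).
#' @param peak_width_sigma Gaussian peak sigma in Da.
#' @export
noise_none <- function(peak_width_sigma = 0.08) {
  noise_spec(baseline_amplitude = 0, baseline_decay = 0, mz_jitter_sd = 0,
             intensity_cv = 0, additive_noise_sd = 0, dropout_prob = 0,
             peak_width_sigma = peak_width_sigma)
}

#' Cohort design for the simulator
#'
#' @param groups Named integer vector of per-group sample counts, e.g.
#'   `c(HC = 20, COPD = 20)`. The first group is the control/reference.
#' @param age_mean,age_sd Per-group age distribution (years); scalars are
#'   recycled. Defaults are balanced across groups.
#' @param sex_male Per-group fraction of male subjects; recycled.
#' @param replicates Technical replicates per sample.
#' @param seed Master seed; all cohort randomness derives from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = c(HC = 20, COPD = 20), age_mean = 65,
                        age_sd = 8, sex_male = 0.6, replicates = 1,
                        seed = 1) {
  stopifnot(length(groups) >= 1, all(groups >= 1), !is.null(names(groups)),
            replicates >= 1)
  k <- length(groups)
  structure(list(
    groups = groups,
    age_mean = rep_len(age_mean, k), age_sd = rep_len(age_sd, k),
    sex_male = rep_len(sex_male, k),
    replicates = as.integer(replicates), seed = as.integer(seed)
  ), class = "cohort_spec")
}

.sdlog_from_cv <- function(cv) sqrt(log(1 + cv^2))

# Adduct m/z of every template peak, in template order (one row per
# template x adduct), with template index, used by the simulators.
.template_peaks <- function(templates) {
  rules <- adduct_rules()
  do.call(rbind, lapply(seq_along(templates), function(i) {
    tp <- templates[[i]]
    data.frame(template = i, name = tp$name, adduct = tp$adducts,
               mz = adduct_mz(tp$monoisotopic_mass, tp$adducts, rules),
               stringsAsFactors = FALSE)
  }))
}

#' Build a metabolite template library with planted differential features
#'
#' Creates `n_background` null metabolites plus `n_differential` planted
#' markers drawn from the embedded reference set ([metabolite_db()]), each
#' carrying a Na+/K+ cation adduct whose m/z lies in the 100-400 Da window.
#' The first half (rounded up) of the planted markers is up-regulated in
#' the case group, the rest down-regulated, each with standardized effect
#' `effect_size` on log intensity. Background peak positions are packed so
#' that no two peaks lie closer than `4 * peak_width_sigma`.
#'
#' @param n_background Number of null (non-differential) metabolites.
#' @param n_differential Number of planted differential metabolites
#'   (at most the size of the embedded reference set).
#' @param effect_size Standardized effect (Cohen's d on log intensity).
#' @param groups Character vector of group labels; the last is the case
#'   group carrying the effects, all others have shift 0.
#' @param peak_width_sigma Gaussian sigma used for the packing guarantee.
#' @param seed Integer seed.
#' @return A list with `templates` (list of metabolite templates) and
#'   `truth` (ground-truth manifest: data.frame `differential_features`
#'   with name/mz/adduct/direction/effect, and `null_features` m/z vector).
#' @export
build_template_library <- function(n_background = 300, n_differential = 8,
                                   effect_size = 1.5,
                                   groups = c("SCOPD", "AECOPD"),
                                   peak_width_sigma = 0.08, seed = 1) {
  stopifnot(n_background >= 0, n_differential >= 0, effect_size >= 0,
            length(groups) >= 2)
  set.seed(seed)
  window <- c(100, 400)
  margin <- 2
  min_gap <- 4 * peak_width_sigma
  rules <- adduct_rules()
  case <- groups[length(groups)]

  db <- metabolite_db()
  if (n_differential > nrow(db)) {
    stop("n_differential exceeds the embedded reference set (",
         nrow(db), " metabolites)")
  }

  taken <- numeric(0) # occupied m/z positions
  templates <- list()
  truth_rows <- list()

  if (n_differential > 0) {
    n_up <- ceiling(n_differential / 2)
    placed <- 0L
    for (i in seq_len(nrow(db))) {
      if (placed >= n_differential) break
      rec <- db[i, ]
      # prefer the Na+/K+ cation adducts; fall back to [M+H]+ if neither
      # fits; reference metabolites whose adducts all collide with peaks
      # already placed (real masses do collide at unit resolution) are
      # skipped in favour of the next reference entry
      cand <- c(sample(c("[M+Na]+", "[M+K]+")), "[M+H]+")
      mz <- adduct_mz(rec$monoisotopic_mass, cand, rules)
      ok <- mz >= window[1] + margin & mz <= window[2] - margin &
        vapply(mz, function(z) !length(taken) || min(abs(z - taken)) >= min_gap,
               logical(1))
      if (!any(ok)) next
      placed <- placed + 1L
      pick <- which(ok)[1]
      direction <- if (placed <= n_up) "up" else "down"
      eff <- if (direction == "up") effect_size else -effect_size
      ge <- stats::setNames(rep(0, length(groups)), groups)
      ge[case] <- eff
      templates[[length(templates) + 1]] <- list(
        name = rec$name, formula = rec$formula,
        monoisotopic_mass = rec$monoisotopic_mass,
        adducts = cand[pick],
        base_log_intensity = stats::runif(1, log(2000), log(8000)),
        group_effects = ge
      )
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        name = rec$name, mz = mz[pick], adduct = cand[pick],
        direction = direction, effect = eff, stringsAsFactors = FALSE
      )
      taken <- c(taken, mz[pick])
    }
    if (placed < n_differential) {
      stop("could only place ", placed, " of ", n_differential,
           " differential metabolites from the embedded reference set")
    }
  }

  null_mz <- numeric(0)
  if (n_background > 0) {
    # evenly spaced candidate slots with random jitter; refuse infeasible packs
    span <- diff(window) - 2 * margin
    n_all <- n_background + n_differential
    spacing <- span / (n_all * 1.08)
    if (spacing < min_gap) {
      stop("infeasible packing: ", n_all, " peaks need spacing ",
           signif(min_gap, 3), " Da but only ", signif(spacing, 3),
           " Da is available in the 100-400 Da window")
    }
    slots <- seq(window[1] + margin, window[2] - margin, by = spacing)
    free <- slots[vapply(slots, function(z)
      !length(taken) || min(abs(z - taken)) >= 2 * min_gap, logical(1))]
    if (length(free) < n_background) stop("infeasible packing: too few free slots")
    pos <- sort(sample(free, n_background))
    # jitter keeps slot separation >= min_gap and stays clear of the
    # 2*min_gap exclusion zone around differential peaks
    jit <- min((spacing - min_gap) / 2, min_gap)
    pos <- pos + stats::runif(n_background, -jit, jit)
    add <- sample(rules$name, n_background, replace = TRUE,
                  prob = c(0.2, 0.4, 0.4))
    shift <- rules$mass_shift[match(add, rules$name)]
    base <- stats::rnorm(n_background, mean = 6.2, sd = 1.0)
    ge0 <- stats::setNames(rep(0, length(groups)), groups)
    for (j in seq_len(n_background)) {
      templates[[length(templates) + 1]] <- list(
        name = sprintf("bg_%03d", j), formula = NA_character_,
        monoisotopic_mass = pos[j] - shift[j],
        adducts = add[j], base_log_intensity = base[j],
        group_effects = ge0
      )
    }
    null_mz <- pos
  }

  truth <- list(
    differential_features = if (length(truth_rows)) do.call(rbind, truth_rows)
      else data.frame(name = character(), mz = numeric(), adduct = character(),
                      direction = character(), effect = numeric(),
                      stringsAsFactors = FALSE),
    null_features = null_mz,
    groups = groups, case_group = case, seed = seed
  )
  list(templates = templates, truth = truth)
}

#' Simulate one LDI mass spectrum
#'
#' Decaying exponential baseline plus one Gaussian peak per template adduct
#' (m/z jittered, log-normal intensity variation, independent dropout) plus
#' additive Gaussian noise, clipped at zero.
#'
#' @param templates Template list from [build_template_library()].
#' @param group Group label of the sample (must appear in every template's
#'   `group_effects`).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param grid_step m/z grid spacing in Da; default `peak_width_sigma / 4`.
#' @param sample_id Sample identifier stored in the spectrum.
#' @return An object of class `ldi_spectrum`: list with `mz`, `intensity`,
#'   `sample_id`, `metadata`.
#' @export
simulate_spectrum <- function(templates, group, noise = noise_spec(),
                              seed = 1, grid_step = NULL,
                              sample_id = "sample") {
  if (!length(templates)) stop("empty template list")
  if (is.null(grid_step)) grid_step <- noise$peak_width_sigma / 4
  stopifnot(grid_step <= noise$peak_width_sigma / 3)
  set.seed(seed)
  mz <- seq(100, 400, by = grid_step)
  n <- length(mz)
  intensity <- noise$baseline_amplitude * exp(-noise$baseline_decay * (mz - 100))
  sdlog <- .sdlog_from_cv(noise$intensity_cv)
  sig <- noise$peak_width_sigma
  for (tp in templates) {
    if (!group %in% names(tp$group_effects)) {
      stop("group '", group, "' missing from group_effects of '", tp$name, "'")
    }
    shift <- tp$group_effects[[group]] * sdlog
    for (ad in tp$adducts) {
      if (noise$dropout_prob > 0 && stats::runif(1) < noise$dropout_prob) next
      center <- adduct_mz(tp$monoisotopic_mass, ad) +
        stats::rnorm(1, 0, noise$mz_jitter_sd)
      height <- exp(tp$base_log_intensity + shift +
                      stats::rnorm(1, 0, sdlog))
      lo <- max(1L, ceiling((center - 6 * sig - 100) / grid_step) + 1L)
      hi <- min(n, floor((center + 6 * sig - 100) / grid_step) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      intensity[idx] <- intensity[idx] +
        height * exp(-(mz[idx] - center)^2 / (2 * sig^2))
    }
  }
  if (noise$additive_noise_sd > 0) {
    intensity <- intensity + stats::rnorm(n, 0, noise$additive_noise_sd)
  }
  intensity <- pmax(intensity, 0)
  structure(list(mz = mz, intensity = intensity, sample_id = sample_id,
                 metadata = list(group = group, seed = seed)),
            class = "ldi_spectrum")
}

#' Simulate a full cohort of spectra with metadata
#'
#' One spectrum per sample per replicate. Ages and sexes are drawn from the
#' per-group distributions of the [cohort_spec()]; per-spectrum seeds are
#' split deterministically from the master seed (drawn once from the seeded
#' RNG and recorded), so the same spec reproduces the cohort byte for byte.
#'
#' @param spec A [cohort_spec()].
#' @param templates Template list from [build_template_library()].
#' @param noise A [noise_spec()].
#' @return An object of class `ldi_cohort`: list with `spectra` (list of
#'   [simulate_spectrum()] results), `metadata` (data.frame with sample_id,
#'   group, age, sex, replicate, spectrum_seed) and `seed`.
#' @export
simulate_cohort <- function(spec, templates, noise = noise_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  glab <- names(spec$groups)
  meta <- do.call(rbind, lapply(seq_along(glab), function(g) {
    n <- spec$groups[[g]]
    data.frame(
      group = glab[g],
      age = round(stats::rnorm(n, spec$age_mean[g], spec$age_sd[g]), 1),
      sex = ifelse(stats::runif(n) < spec$sex_male[g], "M", "F"),
      stringsAsFactors = FALSE
    )
  }))
  meta <- meta[rep(seq_len(nrow(meta)), each = spec$replicates), ]
  meta$replicate <- rep(seq_len(spec$replicates),
                        times = nrow(meta) / spec$replicates)
  base_id <- rep(seq_len(sum(spec$groups)), each = spec$replicates)
  meta$sample_id <- sprintf("S%03d_r%d", base_id, meta$replicate)
  meta$spectrum_seed <- sample.int(.Machine$integer.max - 1L, nrow(meta))
  rownames(meta) <- NULL
  meta <- meta[, c("sample_id", "group", "age", "sex", "replicate",
                   "spectrum_seed")]
  spectra <- lapply(seq_len(nrow(meta)), function(i) {
    simulate_spectrum(templates, group = meta$group[i], noise = noise,
                      seed = meta$spectrum_seed[i],
                      sample_id = meta$sample_id[i])
  })
  structure(list(spectra = spectra, metadata = meta, seed = spec$seed),
            class = "ldi_cohort")
}

#' Simulate an aligned feature matrix directly from a template library
#'
#' Shortcut past the spectral stage: draws per-sample peak intensities from
#' the same log-normal model as [simulate_spectrum()] (dropout sets the
#' entry to 0), one feature per template adduct, already aligned on the
#' theoretical adduct m/z. Used for classifier and screening calibration
#' studies where the spectral stage is exercised separately.
#'
#' @inheritParams simulate_cohort
#' @return A [feature_matrix()] with group labels attached.
#' @export
simulate_feature_matrix <- function(spec, templates, noise = noise_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  known <- names(templates[[1]]$group_effects)
  if (!all(names(spec$groups) %in% known)) {
    stop("cohort groups not covered by the template library: ",
         paste(setdiff(names(spec$groups), known), collapse = ", "))
  }
  set.seed(spec$seed)
  pk <- .template_peaks(templates)
  ord <- order(pk$mz)
  pk <- pk[ord, ]
  sdlog <- .sdlog_from_cv(noise$intensity_cv)
  glab <- rep(names(spec$groups), times = spec$groups)
  n <- length(glab)
  base <- vapply(templates, function(tp) tp$base_log_intensity, numeric(1))
  eff_by_group <- vapply(names(spec$groups), function(g)
    vapply(templates, function(tp) tp$group_effects[[g]], numeric(1)),
    numeric(length(templates)))
  vals <- matrix(0, n, nrow(pk))
  for (i in seq_len(n)) {
    mu <- base[pk$template] + eff_by_group[pk$template, glab[i]] * sdlog
    x <- exp(stats::rnorm(nrow(pk), mu, sdlog))
    if (noise$dropout_prob > 0) {
      x[stats::runif(nrow(pk)) < noise$dropout_prob] <- 0
    }
    vals[i, ] <- x
  }
  feature_matrix(vals, feature_mz = pk$mz,
                 sample_ids = sprintf("S%03d", seq_len(n)),
                 labels = glab)
}
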