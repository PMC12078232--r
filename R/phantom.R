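#' Planted effect specification for synthetic cohorts
#'
#' Encodes the statistical ground truth a synthetic cohort is generated
#' from. The defaults emulate the study conditions the analyses are
#' designed for: a 180-patient-scale SCLC cohort with roughly half the
#' patients relapsing, hilar stations (10R/10L) and stations 4R/7 dominating
#' both nodal involvement and recurrence, an exponential time-to-recurrence
#' with a hazard ratio of 1.635 for tumors of 5 cm or larger, and random
#' censoring giving a median follow-up of around three years.
#'
#' `logit_coefficients` are log-odds per standard deviation: the planted
#' recurrence label is drawn from a logistic model applied to the cohort's
#' z-scored true feature values, so coefficients are comparable across
#' features of different scales. All defaults are artifact choices for the
#' generator, not estimates from data.
#'
#' @param involved_station_probs named 16-vector, per-station probability
#'   that the patient's initial nodal disease involves the station.
#' @param logit_intercept intercept of the planted recurrence model.
#' @param logit_coefficients named numeric vector of per-SD log-odds on
#'   feature names from [feature_names()].
#' @param baseline_hazard events/month for relapsing patients.
#' @param hazard_ratio_per_unit named numeric vector of multiplicative
#'   hazard ratios; supported covariate keys: `tumor_ge5cm`, `age_ge60`,
#'   `male`, `tumor_diameter_cm`, `smoking_index`.
#' @param censoring_rate events/month of the independent censoring process
#'   (0 disables random censoring).
#' @param followup_cap_months administrative cap used when neither an event
#'   nor a censoring time is finite.
#' @param margin_mm CTV dilation margin around gross disease, in mm at the
#'   reference 144 mm extent (scaled with the grid).
#' @param recurrence_station_weights named 16-vector of relative weights
#'   used to pick the station a recurrence is planted in.
#' @param p_recurrence_at_gross probability that a planted recurrence is
#'   seeded at the patient's own gross disease (GTV-affected) rather than
#'   elsewhere.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(involved_station_probs = NULL,
                        logit_intercept = 0.1,
                        logit_coefficients = c(
                          RgtvLN13 = 1.2, RgtvLN14 = 1.0, RctvLN7 = 1.0,
                          RctvLN11 = 1.0, gtv_size = 1.0),
                        baseline_hazard = 0.04,
                        hazard_ratio_per_unit = c(tumor_ge5cm = 1.635),
                        censoring_rate = 1 / 60,
                        followup_cap_months = 120,
                        margin_mm = 8,
                        recurrence_station_weights = NULL,
                        p_recurrence_at_gross = 105 / 170) {
  labs <- station_labels()
  if (is.null(involved_station_probs)) {
    involved_station_probs <- setNames(
      c(0.05, 0.05, 0.15, 0.03, 0.05, 0.03, 0.35, 0.08,
        0.08, 0.12, 0.30, 0.05, 0.45, 0.35, 0.15, 0.15), labs)
  }
  if (is.null(recurrence_station_weights)) {
    # relative station weights mirroring the recurrence prevalence pattern
    # the cohort is meant to emulate (hilar and right paratracheal dominant)
    recurrence_station_weights <- setNames(
      c(3, 2, 8, 0, 3, 0, 24, 3, 3, 10, 18, 2, 50, 23, 11, 10), labs)
  }
  involved_station_probs <- involved_station_probs[labs]
  recurrence_station_weights <- recurrence_station_weights[labs]
  stopifnot(!anyNA(involved_station_probs),
            all(involved_station_probs >= 0 & involved_station_probs <= 1),
            !anyNA(recurrence_station_weights),
            all(recurrence_station_weights >= 0),
            baseline_hazard > 0, censoring_rate >= 0,
            p_recurrence_at_gross >= 0, p_recurrence_at_gross <= 1,
            margin_mm >= 0)
  if (is.null(names(logit_coefficients)) && length(logit_coefficients) > 0) {
    ctv_stop("ctv_effect_error", "logit_coefficients must be named by feature")
  }
  structure(list(
    involved_station_probs = involved_station_probs,
    logit_intercept = logit_intercept,
    logit_coefficients = logit_coefficients,
    baseline_hazard = baseline_hazard,
    hazard_ratio_per_unit = hazard_ratio_per_unit,
    censoring_rate = censoring_rate,
    followup_cap_months = followup_cap_months,
    margin_mm = margin_mm,
    recurrence_station_weights = recurrence_station_weights,
    p_recurrence_at_gross = p_recurrence_at_gross
  ), class = "effect_spec")
}

# hazard covariate transforms the hazard-ratio map may refer to
hazard_covariate <- function(record, key) {
  switch(key,
         tumor_ge5cm = as.numeric(record$tumor_diameter_cm >= 5),
         age_ge60 = as.numeric(record$age_years >= 60),
         male = as.numeric(record$sex == "male"),
         tumor_diameter_cm = record$tumor_diameter_cm,
         smoking_index = record$smoking_index,
         ctv_stop("ctv_effect_error", "unknown hazard covariate '%s'", key))
}

sample_categorical <- function(values, probs) {
  values[sample.int(length(values), 1L, prob = probs)]
}

#' Generate one synthetic patient
#'
#' Builds one patient's geometry on the atlas grid and samples the clinical
#' covariates. The primary tumor (GTV) is an ellipsoid placed in the
#' sampled lung quadrant with a sampled diameter; nodal gross disease
#' (GTVnd) is a sub-region of each involved station; the CTV is the
#' morphological dilation of GTV plus GTVnd by the margin, unioned with the
#' full masks of the involved stations and clipped to the grid. Relapse
#' label, follow-up time and recurrence mask are assigned at cohort level
#' (see [generate_cohort()]), because the planted recurrence model acts on
#' cohort-standardized features.
#'
#' All geometric sizes scale with the grid's physical extent, so the same
#' anatomy is produced (relatively) on a small test grid and the default
#' 96^3 grid.
#'
#' @param atlas a `station_atlas` from [generate_atlas()].
#' @param effect an [effect_spec()].
#' @param seed integer seed for this patient's substream.
#' @param id patient identifier.
#' @param margin_mm CTV margin override; default taken from `effect`
#'   (scaled with the grid).
#' @return list with elements `ss` ([structure_set()]), `record`
#'   ([patient_record()]) and `involved` (logical 16-vector).
#' @export
generate_patient <- function(atlas, effect = effect_spec(), seed = 1L,
                             id = "p001", margin_mm = NULL) {
  stopifnot(inherits(atlas, "station_atlas"), inherits(effect, "effect_spec"))
  grid <- atlas$grid
  ext <- grid_extent_mm(grid)
  s <- min(ext) / 144 # geometric scale relative to the reference layout
  if (is.null(margin_mm)) margin_mm <- effect$margin_mm * s
  with_seed(seed, {
    lung_area <- sample_categorical(1:4, c(0.3, 0.2, 0.3, 0.2))
    # quadrant codes: 1 right-upper, 2 right-lower, 3 left-upper, 4 left-lower
    xf <- if (lung_area %in% c(1, 2)) runif(1, 0.13, 0.24) else runif(1, 0.76, 0.87)
    zf <- if (lung_area %in% c(1, 3)) runif(1, 0.60, 0.75) else runif(1, 0.25, 0.40)
    yf <- runif(1, 0.42, 0.58)
    diameter_cm <- min(max(rnorm(1, 4.8, 1.6), 1.5), 9)
    gtv_center <- grid$origin + c(xf, yf, zf) * ext
    gtv_semi <- pmax(diameter_cm * 10 / 2 * s * runif(3, 0.85, 1.15),
                     grid$spacing * 0.75)
    gtv <- rasterize_ellipsoid(grid, gtv_center, gtv_semi)
    if (!any(gtv)) { # guarantee a non-empty primary even on coarse grids
      ctr <- pmin(pmax(round((gtv_center - grid$origin) / grid$spacing) + 1, 1),
                  grid$shape)
      gtv[ctr[1], ctr[2], ctr[3]] <- TRUE
    }

    involved <- runif(16) < effect$involved_station_probs
    gtvnd <- array(FALSE, grid$shape)
    for (i in which(involved)) {
      ctr <- atlas$spec$station_centers[i, ] +
        runif(3, -0.15, 0.15) * atlas$spec$station_radii[i, ]
      semi <- atlas$spec$station_radii[i, ] * runif(3, 0.45, 0.8)
      sub <- rasterize_ellipsoid(grid, ctr, semi) & atlas$masks[[i]]
      if (!any(sub)) {
        ctr_vox <- pmin(pmax(round((atlas$spec$station_centers[i, ] - grid$origin) /
                                     grid$spacing) + 1, 1), grid$shape)
        sub[ctr_vox[1], ctr_vox[2], ctr_vox[3]] <- atlas$masks[[i]][ctr_vox[1], ctr_vox[2], ctr_vox[3]]
        if (!any(sub)) { # centre voxel fell outside the rasterized station
          first <- which(atlas$masks[[i]])[1]
          sub[first] <- TRUE
        }
      }
      gtvnd <- gtvnd | sub
    }

    ctv <- dilate_mask(gtv | gtvnd, grid, margin_mm)
    for (i in which(involved)) ctv <- ctv | atlas$masks[[i]]

    smoking_group <- sample_categorical(1:3, c(0.328, 0.067, 0.605))
    record <- patient_record(
      id = id,
      age_years = min(max(rnorm(1, 61, 10), 30), 88),
      sex = sample_categorical(c("male", "female"), c(0.722, 0.278)),
      t_stage = sample_categorical(paste0("T", 1:4), c(28, 47, 21, 84)),
      n_stage = sample_categorical(paste0("N", 0:3), c(6, 8, 82, 84)),
      tnm_stage = sample_categorical(c("I", "II", "III", "IV"), c(4, 4, 158, 14)),
      smoking_index = switch(smoking_group, 0, runif(1, 50, 400), runif(1, 400, 1500)),
      tumor_diameter_cm = diameter_cm,
      tumor_location = sample_categorical(c("central", "peripheral"), c(0.756, 0.244)),
      chemo = sample_categorical(c("synchronous", "sequential"), c(0.661, 0.339)),
      followup_months = 0,
      relapse = 0L,
      lung_area_code = lung_area
    )
    ss <- structure_set(grid, ctv = ctv, gtv = gtv, gtvnd = gtvnd,
                        ln = atlas$masks, validate = TRUE)
    list(ss = ss, record = record,
         involved = setNames(involved, station_labels()),
         gtv_geometry = list(center = gtv_center, semi_axes = gtv_semi))
  })
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Generates `n` patients on a shared atlas, extracts their true feature
#' vectors, draws the relapse label of each patient from the planted
#' logistic model applied to the cohort-standardized features, draws
#' exponential time-to-recurrence with covariate-dependent hazard and an
#' independent censoring time (observed follow-up is the minimum of the
#' two), and plants a recurrence ellipsoid inside a weighted-sampled
#' station for every relapsing patient. All randomness descends from
#' `seed` through labelled per-patient substreams, so cohorts are
#' reproducible.
#'
#' @param n number of patients (>= 2).
#' @param atlas a `station_atlas`; defaults to [generate_atlas()] on the
#'   default grid.
#' @param effect an [effect_spec()].
#' @param seed master seed for the cohort.
#' @param out_dir optional directory; when given, each patient is written
#'   as a mask directory via [save_structure_set()] plus a cohort-level
#'   `truth.json`.
#' @return An object of class `ctv_cohort`: list with `patients` (each a
#'   list `ss`, `record`, `involved`), `features` (data frame from
#'   [extract_cohort_features()]), `outcomes` (data frame of id, time,
#'   event, relapse, planted probability) and `truth` (all planted
#'   parameters and per-patient latent values).
#' @export
generate_cohort <- function(n, atlas = NULL, effect = effect_spec(),
                            seed = 1L, out_dir = NULL) {
  if (n < 2) ctv_stop("ctv_cohort_error", "a cohort needs n >= 2 patients")
  if (is.null(atlas)) atlas <- generate_atlas()
  patients <- lapply(seq_len(n), function(i) {
    generate_patient(atlas, effect,
                     seed = substream_seed(seed, "patient", i),
                     id = sprintf("p%04d", i))
  })
  feats <- extract_cohort_features(patients)
  X <- as.matrix(feats[, feature_names()])

  # planted logistic recurrence model on cohort-standardized features
  mu <- colMeans(X)
  sd_pop <- sqrt(colMeans(sweep(X, 2, mu)^2))
  Z <- sweep(X, 2, mu)
  nz <- sd_pop > 0
  Z[, nz] <- sweep(Z[, nz, drop = FALSE], 2, sd_pop[nz], `/`)
  Z[, !nz] <- 0
  coefs <- effect$logit_coefficients
  if (length(coefs) > 0 && !all(names(coefs) %in% colnames(Z))) {
    ctv_stop("ctv_effect_error", "unknown feature(s) in logit_coefficients: %s",
             paste(setdiff(names(coefs), colnames(Z)), collapse = ", "))
  }
  lp <- effect$logit_intercept +
    if (length(coefs) > 0) drop(Z[, names(coefs), drop = FALSE] %*% coefs) else 0
  p_relapse <- plogis(lp)
  relapse <- with_seed(substream_seed(seed, "relapse"),
                       rbinom(n, 1L, p_relapse))

  # survival: exponential event times for relapsers, independent censoring
  out <- with_seed(substream_seed(seed, "survival"), {
    t(vapply(seq_len(n), function(i) {
      rec <- patients[[i]]$record
      haz <- effect$baseline_hazard
      for (key in names(effect$hazard_ratio_per_unit)) {
        haz <- haz * effect$hazard_ratio_per_unit[[key]]^hazard_covariate(rec, key)
      }
      ev <- if (relapse[i] == 1L) rexp(1, haz) else Inf
      cs <- if (effect$censoring_rate > 0) rexp(1, effect$censoring_rate) else Inf
      tm <- min(ev, cs)
      if (!is.finite(tm)) tm <- effect$followup_cap_months
      c(time = tm, event = as.numeric(is.finite(ev) && ev <= cs), latent_event = ev)
    }, numeric(3)))
  })

  rec_station <- rep(NA_character_, n)
  with_seed(substream_seed(seed, "recurrence_masks"), {
    for (i in seq_len(n)) {
      patients[[i]]$record$relapse <- relapse[i]
      patients[[i]]$record$followup_months <- out[i, "time"]
      if (relapse[i] == 1L) {
        planted <- plant_recurrence(patients[[i]], atlas, effect)
        patients[[i]]$ss$recurrence <- planted$mask
        rec_station[i] <- planted$station
      }
    }
  })
  feats$relapse <- relapse

  truth <- list(
    effect = effect,
    atlas_spec = atlas$spec,
    seed = seed,
    feature_center = mu, feature_scale = sd_pop,
    per_patient = data.frame(
      id = feats$id, lp = lp, p_relapse = p_relapse, relapse = relapse,
      time = out[, "time"], event = out[, "event"],
      latent_event_time = out[, "latent_event"],
      recurrence_station = rec_station, stringsAsFactors = FALSE)
  )
  cohort <- structure(list(patients = patients, grid = atlas$grid,
                           features = feats, outcomes = truth$per_patient,
                           truth = truth),
                      class = "ctv_cohort")
  if (!is.null(out_dir)) save_cohort(cohort, out_dir)
  cohort
}

# plant one connected recurrence ellipsoid; multi-station events arise
# naturally when it straddles a station boundary
plant_recurrence <- function(patient, atlas, effect) {
  grid <- atlas$grid
  w <- effect$recurrence_station_weights
  involved <- patient$involved
  at_gross <- runif(1) < effect$p_recurrence_at_gross && any(involved)
  pool <- if (at_gross) which(involved) else seq_len(16)
  wp <- w[pool]
  if (sum(wp) == 0) wp <- rep(1, length(pool))
  st <- pool[sample.int(length(pool), 1L, prob = wp)]
  if (at_gross) {
    # seed at this patient's nodal disease inside the station
    vox <- which(patient$ss$gtvnd & atlas$masks[[st]], arr.ind = TRUE)
    center <- if (nrow(vox) > 0) {
      grid$origin + (colMeans(vox) - 1) * grid$spacing
    } else {
      atlas$spec$station_centers[st, ]
    }
  } else {
    center <- atlas$spec$station_centers[st, ] +
      runif(3, -0.3, 0.3) * atlas$spec$station_radii[st, ]
  }
  semi <- pmax(atlas$spec$station_radii[st, ] * runif(3, 0.55, 1.05),
               grid$spacing * 0.75)
  mask <- rasterize_ellipsoid(grid, center, semi)
  if (!any(mask)) {
    ctr <- pmin(pmax(round((center - grid$origin) / grid$spacing) + 1, 1),
                grid$shape)
    mask[ctr[1], ctr[2], ctr[3]] <- TRUE
  }
  list(mask = mask, station = station_labels()[st])
}

#' @rdname generate_cohort
#' @param cohort a `ctv_cohort`.
#' @export
save_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "ctv_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (p in cohort$patients) {
    save_structure_set(p$ss, file.path(out_dir, p$record$id), record = p$record)
  }
  truth <- cohort$truth
  truth$effect <- unclass(truth$effect)
  truth$atlas_spec <- list(
    grid = unclass(truth$atlas_spec$grid),
    station_centers = truth$atlas_spec$station_centers,
    station_radii = truth$atlas_spec$station_radii)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns")
  invisible(out_dir)
}
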