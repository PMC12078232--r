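#' Simulate a cohort at the feature-vector level
#'
#' Draws 110-parameter feature vectors directly from a generative model of
#' station involvement, without rasterizing voxel phantoms, and plants the
#' same logistic recurrence model as [generate_cohort()]. This is the fast
#' path for statistical experiments on the screening and prediction stages
#' (hundreds of patients, many replicates), where the voxel geometry is
#' irrelevant but the feature schema and its dependence structure matter:
#' involved stations are fully covered by the CTV (ratio 1) and carry
#' gross disease, neighbouring stations get partial coverage, the `RI*`
#' families share the ideal-CTV denominator, and `Rcmg = Rctv - Rgtv`
#' holds exactly.
#'
#' @param n number of patients (>= 2).
#' @param effect an [effect_spec()]; uses `involved_station_probs`,
#'   `logit_intercept` and `logit_coefficients`.
#' @param seed integer seed.
#' @return list with `features` (data frame: `id`, 110 feature columns,
#'   `relapse`) and `truth` (per-patient linear predictor and probability,
#'   names of the informative features).
#' @export
simulate_feature_cohort <- function(n, effect = effect_spec(), seed = 1L) {
  if (n < 2) ctv_stop("ctv_cohort_error", "a cohort needs n >= 2 patients")
  stopifnot(inherits(effect, "effect_spec"))
  spec <- atlas_spec() # nominal station volumes from the canonical layout
  w_station <- 4 / 3 * pi * apply(spec$station_radii, 1, prod)

  sim <- with_seed(substream_seed(seed, "feature_cohort"), {
    probs <- effect$involved_station_probs
    involved <- matrix(runif(n * 16) < rep(probs, each = n), n, 16)
    # partial CTV spill-over into uninvolved stations (dilation effect)
    partial <- matrix(runif(n * 16) < 0.25, n, 16) & !involved
    rctv <- matrix(0, n, 16)
    rctv[involved] <- 1
    rctv[partial] <- rbeta(sum(partial), 1.2, 3)
    rgtv <- matrix(0, n, 16)
    rgtv[involved] <- runif(sum(involved), 0.15, 0.75)
    rcmg <- rctv - rgtv

    wmat <- matrix(w_station, n, 16, byrow = TRUE)
    touched <- rctv > 0
    idea <- rowSums(wmat * touched)
    safe_idea <- ifelse(idea > 0, idea, 1)
    rictv <- rctv * wmat / safe_idea * touched
    rigtv <- rgtv * wmat / safe_idea * touched
    ricmg <- rcmg * wmat / safe_idea * touched

    diameter <- pmin(pmax(rnorm(n, 4.8, 1.6), 1.5), 9)
    gtv_vol <- 4 / 3 * pi * (diameter * 10 / 2)^3
    ctv_vol <- rowSums(wmat * rctv) + gtv_vol * runif(n, 1.2, 1.8)
    gtvnd_vol <- rowSums(wmat * rgtv)
    resol <- round(runif(n, 0.89, 1.37), 4)
    lung_area <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.2, 0.3, 0.2))
    flags <- (touched[, ln_index(overlap_flag_stations()), drop = FALSE]) + 0

    X <- cbind(rctv, rictv, rgtv, rigtv, rcmg, ricmg,
               ctv_vol, gtvnd_vol, resol,
               rowSums(touched), rowSums(involved), lung_area,
               flags, diameter)
    colnames(X) <- feature_names()
    X
  })

  mu <- colMeans(sim)
  sd_pop <- sqrt(colMeans(sweep(sim, 2, mu)^2))
  Z <- sweep(sim, 2, mu)
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
  relapse <- with_seed(substream_seed(seed, "feature_relapse"),
                       rbinom(n, 1L, p_relapse))

  features <- data.frame(id = sprintf("p%04d", seq_len(n)), sim,
                         relapse = relapse, stringsAsFactors = FALSE,
                         check.names = FALSE)
  list(features = features,
       truth = list(lp = lp, p_relapse = p_relapse,
                    informative = names(coefs), effect = effect))
}
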