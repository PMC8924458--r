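# Synthetic survey cohorts with a latent-Gaussian item model:
#
#   latent score ~ MVN(mu, D R D)  ->  clamp to [-2, +2]
#   item         = round(clamp(latent + N(0, item_noise_sd)))   (multi-item)
#   I, B         = round(clamp(latent))                          (single item)
#
# Clamping near the scale boundary and integer rounding bias the observed
# score moments and attenuate correlations relative to the latent targets, so
# the generator supports a seeded fixed-point Monte-Carlo calibration that
# tunes the latent means/SDs/correlations until the *observed* construct
# scores hit the targets (see calibrate_generator()).
#
# Correlation targets involving the composites (BI_*, RAI_*) cannot be rows
# of the latent correlation matrix; they are induced by allocating each such
# target across the composite's constituent constructs proportionally to the
# composite loadings a_j * sd_j, which reproduces the target exactly at the
# latent level (see allocation comment below).

.composite_vars <- c("BI_H", "BI_S", "RAI_H", "RAI_S")

composite_loadings <- function(name, weights_health, weights_sustainability) {
  switch(name,
    BI_H = setNames(as.numeric(weights_health), c("A_H", "SN_H", "PBC_H")),
    BI_S = setNames(as.numeric(weights_sustainability),
                    c("A_S", "SN_S", "PBC_S")),
    RAI_H = setNames(unname(rai_weights),
                     paste0(names(rai_weights), "_H")),
    RAI_S = setNames(unname(rai_weights),
                     paste0(names(rai_weights), "_S")),
    setNames(1, name)  # a base variable loads only on itself
  )
}

#' Synthetic cohort generator configuration
#'
#' Bundles the target moments, correlation structure, survey layout and
#' missing-data plan for [generate_cohort()]. Targets are stated for the
#' *observed* construct scores (after item discretization); see
#' [calibrate_generator()].
#'
#' @param n_participants Completers per cohort (default 144).
#' @param n_starters Total records including incomplete starters
#'   (default 176; must be >= `n_participants`).
#' @param target_means,target_sds Named numeric vectors over score names
#'   (every SD > 0; construct means within `[-2, +2]`).
#' @param target_correlations `NULL` or a data frame `var1, var2, r` with
#'   `|r| <= 1`; names may include the composites `BI_H`, `BI_S`, `RAI_H`,
#'   `RAI_S` provided their constituent constructs are present.
#' @param weights_health,weights_sustainability [tpb_weights()] defining the
#'   BI composites used for induced correlation targets.
#' @param items_per_construct Items per multi-item construct (default 3).
#' @param item_noise_sd SD of the independent item-level Gaussian noise added
#'   to the construct latent before discretization (default 0.5).
#' @param dk_count_behavior Number of participants answering "Don't know" on
#'   a behavior item (default 6).
#' @param dk_items Behavior item(s) receiving the "Don't know" answers
#'   (default `"B_S"`: the printed degrees of freedom place all six on the
#'   sustainability behavior item).
#' @param tpb_block_correlation,sdt_block_correlation Default latent
#'   correlation among constructs of the same TPB block / SDT regulation
#'   block within a topic (defaults 0.3 and 0).
#' @param pd_floor Eigenvalue floor for the positive-definite projection.
#' @param n_cal,calibration_iterations Monte-Carlo sample size and number of
#'   fixed-point iterations used by [calibrate_generator()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 144L,
                             n_starters = 176L,
                             target_means,
                             target_sds,
                             target_correlations = NULL,
                             weights_health = tpb_weights(1.4, 1.0, 0.5),
                             weights_sustainability = tpb_weights(1.6, 0.5, 0.5),
                             items_per_construct = 3L,
                             item_noise_sd = 0.5,
                             dk_count_behavior = 6L,
                             dk_items = "B_S",
                             tpb_block_correlation = 0.3,
                             sdt_block_correlation = 0,
                             pd_floor = 1e-6,
                             n_cal = 40000L,
                             calibration_iterations = 4L) {
  stopifnot(n_participants >= 1, n_starters >= n_participants,
            items_per_construct >= 1, item_noise_sd >= 0,
            dk_count_behavior >= 0, pd_floor > 0)
  vars <- names(target_means)
  if (is.null(vars) || !setequal(vars, names(target_sds))) {
    abort("target_means and target_sds must be named over the same variables.")
  }
  target_sds <- target_sds[vars]
  if (any(target_sds <= 0)) {
    abort("Every target SD must be > 0.")
  }
  if (any(target_means < -2 | target_means > 2)) {
    abort("Target means must lie in the attainable score range [-2, +2].")
  }
  if (!is.null(target_correlations)) {
    tc <- as_tibble(target_correlations)
    stopifnot(all(c("var1", "var2", "r") %in% names(tc)))
    if (any(abs(tc$r) > 1)) {
      abort("Target correlations must lie in [-1, +1].")
    }
    known <- c(vars, .composite_vars)
    bad <- setdiff(c(tc$var1, tc$var2), known)
    if (length(bad) > 0) {
      abort(paste0("Unknown variable(s) in target_correlations: ",
                   paste(bad, collapse = ", ")))
    }
    for (cv in intersect(.composite_vars, c(tc$var1, tc$var2))) {
      need <- names(composite_loadings(cv, weights_health,
                                       weights_sustainability))
      if (!all(need %in% vars)) {
        abort(glue::glue(
          "Composite {cv} in target_correlations requires variables ",
          "{paste(need, collapse = ', ')} among the targets."))
      }
    }
  } else {
    tc <- tibble(var1 = character(), var2 = character(), r = numeric())
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_starters = as.integer(n_starters),
         vars = vars,
         target_means = target_means,
         target_sds = target_sds,
         target_correlations = tc,
         weights_health = weights_health,
         weights_sustainability = weights_sustainability,
         items_per_construct = as.integer(items_per_construct),
         item_noise_sd = item_noise_sd,
         dk_count_behavior = as.integer(dk_count_behavior),
         dk_items = dk_items,
         tpb_block_correlation = tpb_block_correlation,
         sdt_block_correlation = sdt_block_correlation,
         pd_floor = pd_floor,
         n_cal = as.integer(n_cal),
         calibration_iterations = as.integer(calibration_iterations),
         latent = NULL),
    class = "generator_config"
  )
}

#' Default generator calibration: the published study conditions
#'
#' Returns a [generator_config()] whose targets are the published cohort
#' structure: 144 completers of 176 starters; self-report means/SDs
#' I_H (1.38, 0.69), B_H (0.4, 0.86), I_S (0.77, 0.93), B_S (-0.37, 1.03);
#' the ten printed inter-score Pearson correlations; and 6 "Don't know"
#' behavior responders. Construct-level means/SDs are not published; the
#' defaults here are chosen so that the composite equations reproduce the
#' published BI and RAI moments (e.g. health A/SN/PBC means 1.2/0.7/-0.1
#' give BI_H mean 1.4*1.2 + 1.0*0.7 + 0.5*(-0.1) = 2.33; four independent
#' regulations with SD 0.8 give RAI SD sqrt(10)*0.8 = 2.53 vs 2.48).
#'
#' @return A `generator_config`.
#' @export
default_calibration <- function() {
  means <- c(
    I_H = 1.38, B_H = 0.4, I_S = 0.77, B_S = -0.37,
    A_H = 1.2, SN_H = 0.7, PBC_H = -0.1,
    A_S = 0.6, SN_S = 0.42, PBC_S = -0.5,
    RExt_H = 0.3, RIntro_H = 0.18, RId_H = 1.1, RInt_H = 0.9,
    RExt_S = 0.2, RIntro_S = 0.16, RId_S = 1.0, RInt_S = 0.8
  )
  sds <- c(
    I_H = 0.69, B_H = 0.86, I_S = 0.93, B_S = 1.03,
    A_H = 0.67, SN_H = 0.67, PBC_H = 0.67,
    A_S = 0.63, SN_S = 0.63, PBC_S = 0.63,
    RExt_H = 0.8, RIntro_H = 0.8, RId_H = 0.8, RInt_H = 0.8,
    RExt_S = 0.64, RIntro_S = 0.64, RId_S = 0.64, RInt_S = 0.64
  )
  cors <- tibble(
    var1 = c("I_H", "B_H", "I_H", "I_S", "RAI_H",
             "BI_H", "BI_H", "BI_S", "BI_H", "BI_S"),
    var2 = c("I_S", "B_S", "B_H", "B_S", "RAI_S",
             "BI_S", "RAI_H", "RAI_S", "I_H", "I_S"),
    r = c(0.35, 0.40, 0.64, 0.57, 0.49, 0.12, 0.44, 0.23, 0.41, 0.55)
  )
  generator_config(target_means = means, target_sds = sds,
                   target_correlations = cors)
}

# eigenvalue clipping at `floor`, then renormalization to unit diagonal
project_correlation <- function(mat, floor = 1e-6) {
  dn <- dimnames(mat)
  eig <- eigen(mat, symmetric = TRUE)
  vals <- pmax(eig$values, floor)
  out <- eig$vectors %*% (vals * t(eig$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  out <- (out + t(out)) / 2
  dimnames(out) <- dn
  out
}

# Positive-definite completion by alternating projections: clip to PD, then
# restore the specified cells; unspecified cells drift to values that
# accommodate the constraints (instead of staying at 0, which can force a
# harshly non-PD matrix when specified entries form high-correlation cycles).
# Ends on a PD projection, so specified entries may retain a tiny residual.
complete_pd <- function(mat, specified, floor = 1e-6, max_iter = 200,
                        tol = 1e-7) {
  target <- mat[specified]
  out <- mat
  for (i in seq_len(max_iter)) {
    prev <- out
    out <- project_correlation(out, floor)
    out[specified] <- target
    out <- (out + t(out)) / 2
    if (max(abs(out - prev)) < tol) break
  }
  project_correlation(out, floor)
}

#' Complete a partially specified correlation matrix
#'
#' Builds a full correlation matrix from a partial specification:
#' unspecified off-diagonal entries start at 0 (the least-commitment choice),
#' then the matrix is projected to positive definiteness by clipping its
#' eigenvalues at `floor` and renormalizing to unit diagonal. If the
#' projection moves any specified entry by more than `tol`, the partial
#' specification is contradictory and an error reports the worst deviation.
#'
#' @param partial A data frame `var1, var2, r` with `|r| <= 1`.
#' @param vars Character vector of variable names (defaults to those
#'   appearing in `partial`, in order of appearance).
#' @param floor Eigenvalue floor (default 1e-6).
#' @param tol Maximum allowed movement of a specified entry (default 0.02).
#' @return A positive-definite correlation matrix with dimnames `vars`.
#' @export
complete_correlation_matrix <- function(partial, vars = NULL, floor = 1e-6,
                                        tol = 0.02) {
  partial <- as_tibble(partial)
  stopifnot(all(c("var1", "var2", "r") %in% names(partial)))
  if (any(abs(partial$r) > 1)) {
    abort("Specified correlations must lie in [-1, +1].")
  }
  vars <- vars %||% unique(c(rbind(partial$var1, partial$var2)))
  k <- length(vars)
  mat <- diag(k)
  dimnames(mat) <- list(vars, vars)
  for (i in seq_len(nrow(partial))) {
    v1 <- partial$var1[i]; v2 <- partial$var2[i]
    if (v1 == v2) next
    if (!is.na(mat[v1, v2]) && mat[v1, v2] != 0 &&
        abs(mat[v1, v2] - partial$r[i]) > 1e-12) {
      abort(glue::glue("Asymmetric specification for ({v1}, {v2})."))
    }
    mat[v1, v2] <- mat[v2, v1] <- partial$r[i]
  }
  out <- project_correlation(mat, floor)
  dev <- abs(out[cbind(partial$var1, partial$var2)] - partial$r)
  if (length(dev) > 0 && max(dev) > tol) {
    worst <- which.max(dev)
    abort(glue::glue(
      "Partial correlation specification cannot be completed: entry ",
      "({partial$var1[worst]}, {partial$var2[worst]}) = {partial$r[worst]} ",
      "moved by {round(max(dev), 4)} (> {tol}) during the ",
      "positive-definite projection."))
  }
  out
}

# Build the latent correlation matrix for the current working targets.
#
# Allocation of a composite-involving target r(U, V): with disjoint supports
# and loadings a (for U) and b (for V) over base variables with SDs s,
# setting R[j, k] = kappa * (a_j s_j) * (b_k s_k) gives
#   cov(U, V) = kappa * sum((a s)^2) * sum((b s)^2),
# so kappa = r * sd(U) * sd(V) / (sum((a s)^2) * sum((b s)^2)) reproduces the
# target exactly at the latent level. sd(U) is computed from the current
# within-block correlations.
latent_correlation <- function(config, sds, r_values, floor = NULL) {
  vars <- config$vars
  k <- length(vars)
  mat <- diag(k)
  dimnames(mat) <- list(vars, vars)
  spec <- matrix(FALSE, k, k, dimnames = list(vars, vars))

  set_block <- function(members, rho) {
    members <- intersect(members, vars)
    if (length(members) >= 2 && rho != 0) {
      for (a in members) for (b in members) if (a != b) {
        mat[a, b] <<- rho
        spec[a, b] <<- TRUE
      }
    }
  }
  for (sfx in c("H", "S")) {
    set_block(paste0(c("A", "SN", "PBC"), "_", sfx),
              config$tpb_block_correlation)
    set_block(paste0(.sdt_constructs, "_", sfx),
              config$sdt_block_correlation)
  }

  loadings <- function(name) {
    composite_loadings(name, config$weights_health,
                       config$weights_sustainability)
  }
  comp_sd <- function(a) {
    idx <- names(a)
    sub <- mat[idx, idx, drop = FALSE]
    as_ <- a * sds[idx]
    sqrt(drop(t(as_) %*% sub %*% as_))
  }
  tc <- config$target_correlations
  for (i in seq_len(nrow(tc))) {
    a <- loadings(tc$var1[i])
    b <- loadings(tc$var2[i])
    if (length(intersect(names(a), names(b))) > 0) {
      abort(glue::glue(
        "Correlation target ({tc$var1[i]}, {tc$var2[i]}) has overlapping ",
        "composite supports; it cannot be induced independently."))
    }
    as_ <- a * sds[names(a)]
    bs_ <- b * sds[names(b)]
    kappa <- r_values[i] * comp_sd(a) * comp_sd(b) /
      (sum(as_^2) * sum(bs_^2))
    for (j in names(a)) {
      for (l in names(b)) {
        mat[j, l] <- mat[l, j] <- kappa * (a[[j]] * sds[[j]]) *
          (b[[l]] * sds[[l]])
        spec[j, l] <- spec[l, j] <- TRUE
      }
    }
  }
  complete_pd(mat, spec, floor %||% config$pd_floor)
}

# one latent draw: n x length(vars) matrix, clamped to the score range
draw_latent <- function(n, config, means, sds, corr) {
  sigma <- corr * tcrossprod(sds)
  z <- MASS::mvrnorm(n, mu = means, Sigma = sigma)
  z[z < -2] <- -2
  z[z > 2] <- 2
  colnames(z) <- config$vars
  z
}

current_latent <- function(config) {
  config$latent %||% list(means = config$target_means,
                          sds = config$target_sds,
                          r_values = config$target_correlations$r)
}

#' Generate latent construct scores
#'
#' Draws `n_participants` rows from a multivariate normal with the completed
#' latent correlation matrix, scaled and shifted to the latent means/SDs
#' (the raw targets, or the calibrated latent parameters if
#' [calibrate_generator()] has been applied), then truncated (clamped) to
#' `[-2, +2]`. Identical `(config, seed)` give identical tables.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A tibble of continuous scores, one column per configured variable.
#' @export
generate_scores <- function(config, seed) {
  lat <- current_latent(config)
  corr <- latent_correlation(config, lat$sds, lat$r_values)
  withr::with_seed(seed, {
    as_tibble(draw_latent(config$n_participants, config, lat$means,
                          lat$sds, corr))
  })
}

# Emit the integer item matrix for a latent score matrix, one column per
# layout item (RNG state is consumed for item noise; call inside with_seed).
emit_items <- function(latent, config, layout) {
  n <- nrow(latent)
  out <- matrix(NA_integer_, n, nrow(layout),
                dimnames = list(NULL, layout$item))
  for (v in config$vars) {
    parts <- strsplit(v, "_", fixed = TRUE)[[1]]
    con <- parts[1]
    tp <- names(.topic_suffix)[.topic_suffix == parts[2]]
    its <- layout_items(layout, tp, con)
    for (it in its) {
      x <- latent[, v]
      if (length(its) > 1 && config$item_noise_sd > 0) {
        x <- x + rnorm(n, 0, config$item_noise_sd)
      }
      x <- pmin(pmax(x, -2), 2)
      out[, it] <- as.integer(round(x))
    }
  }
  out
}

# observed construct scores straight from an item matrix (same arithmetic as
# construct_scores(), vectorized for calibration use)
score_item_matrix <- function(items, config, layout) {
  out <- matrix(NA_real_, nrow(items), length(config$vars),
                dimnames = list(NULL, config$vars))
  for (v in config$vars) {
    parts <- strsplit(v, "_", fixed = TRUE)[[1]]
    tp <- names(.topic_suffix)[.topic_suffix == parts[2]]
    its <- layout_items(layout, tp, parts[1])
    out[, v] <- rowMeans(items[, its, drop = FALSE])
  }
  out
}

# realized means/sds/target-pair correlations of observed scores
measure_scores <- function(scores, config) {
  w_h <- config$weights_health
  w_s <- config$weights_sustainability
  col_of <- function(name) {
    a <- composite_loadings(name, w_h, w_s)
    drop(scores[, names(a), drop = FALSE] %*% a)
  }
  tc <- config$target_correlations
  r_real <- purrr::map2_dbl(tc$var1, tc$var2, function(v1, v2) {
    cor(col_of(v1), col_of(v2))
  })
  list(means = colMeans(scores), sds = apply(scores, 2, sd), r = r_real)
}

#' Calibrate the latent generator to the observed-score targets
#'
#' Item discretization and clamping at the `[-2, +2]` boundary bias observed
#' score moments away from the latent parameters (e.g. a latent mean of 1.38
#' with SD 0.69 loses about 0.2 to the +2 boundary) and attenuate
#' correlations. This fixed-point Monte-Carlo calibration simulates a large
#' latent table, pushes it through item emission and scoring, and adjusts the
#' latent means (additively), SDs (multiplicatively) and target-pair
#' correlations (multiplicatively, clamped to (-0.98, 0.98)) toward the
#' targets; repeated `calibration_iterations` times. Deterministic given
#' `(config, seed)`. The result is stored in `config$latent` together with
#' the final realized-vs-target diagnostics (including the measured SD
#' attenuation factors).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the calibration draws.
#' @return The config with `$latent` populated.
#' @export
calibrate_generator <- function(config, seed) {
  layout <- default_survey_layout(config$items_per_construct)
  means <- config$target_means
  sds <- config$target_sds
  r_values <- config$target_correlations$r
  meas <- NULL
  withr::with_seed(seed, {
    for (it in seq_len(config$calibration_iterations)) {
      corr <- latent_correlation(config, sds, r_values)
      latent <- draw_latent(config$n_cal, config, means, sds, corr)
      items <- emit_items(latent, config, layout)
      scores <- score_item_matrix(items, config, layout)
      meas <- measure_scores(scores, config)
      means <- means + (config$target_means - meas$means)
      means <- pmin(pmax(means, -2), 2)
      sds <- sds * pmin(pmax(config$target_sds / meas$sds, 0.5), 3)
      tgt <- config$target_correlations$r
      mult_ok <- abs(meas$r) > 0.05 & sign(meas$r) == sign(tgt)
      r_new <- ifelse(mult_ok,
                      r_values * pmin(pmax(tgt / meas$r, 0.3), 3),
                      r_values + (tgt - meas$r))
      r_values <- pmin(pmax(r_new, -0.98), 0.98)
    }
  })
  config$latent <- list(
    means = means, sds = sds, r_values = r_values,
    diagnostics = list(
      realized_means = meas$means,
      realized_sds = meas$sds,
      realized_correlations = meas$r,
      sd_attenuation = meas$sds / sds,
      seed = seed
    )
  )
  config
}

#' Generate a synthetic survey cohort
#'
#' Draws latent scores (see [generate_scores()]), emits the per-item integer
#' responses (construct latent plus independent item noise, rounded to the
#' nearest value in `{-2..+2}`; intention and behavior as single discretized
#' items), marks `dk_count_behavior` randomly chosen completers as
#' "Don't know" on the configured behavior item(s), and appends
#' `n_starters - n_participants` incomplete starter records who answered only
#' the first self-report section (health intention and behavior) before
#' dropping out. If the config has not been calibrated,
#' [calibrate_generator()] is applied first with the same seed.
#'
#' Byte-identical output for identical `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return A `cohort` tibble of `n_starters` records.
#' @export
generate_cohort <- function(config, seed) {
  if (is.null(config$latent)) {
    config <- calibrate_generator(config, seed)
  }
  need <- setdiff(base_score_names(), config$vars)
  if (length(need) > 0) {
    abort(paste0("generate_cohort needs targets for every score; missing: ",
                 paste(need, collapse = ", ")))
  }
  layout <- default_survey_layout(config$items_per_construct)
  lat <- current_latent(config)
  corr <- latent_correlation(config, lat$sds, lat$r_values)
  n_extra <- config$n_starters - config$n_participants
  withr::with_seed(seed, {
    latent <- draw_latent(config$n_starters, config, lat$means, lat$sds, corr)
    items <- emit_items(latent, config, layout)
    # "Don't know" completers on the behavior item(s)
    if (config$dk_count_behavior > 0) {
      who <- sample.int(config$n_participants, config$dk_count_behavior)
      dk_it <- rep_len(config$dk_items, config$dk_count_behavior)
      for (i in seq_along(who)) {
        items[who[i], dk_it[i]] <- likert_dk
      }
    }
    # starters dropped out after the first self-report section
    if (n_extra > 0) {
      starters <- config$n_participants + seq_len(n_extra)
      keep_items <- layout$item[layout$item %in% c("I_H", "B_H")]
      blank <- setdiff(layout$item, keep_items)
      items[starters, blank] <- NA_integer_
    }
  })
  ids <- sprintf("P%03d", seq_len(config$n_starters))
  as_cohort(bind_cols(tibble(participant_id = ids),
                      as_tibble(items)), layout)
}

#' Write a generator provenance sidecar
#'
#' Records the config targets, seed and package version next to a simulated
#' cohort file, as YAML.
#'
#' @param config A [generator_config()].
#' @param seed The seed used for generation.
#' @param path Output path for the sidecar.
#' @return `path`, invisibly.
#' @export
write_generator_provenance <- function(config, seed, path) {
  yaml::write_yaml(list(
    package = "intentgap",
    version = as.character(utils::packageVersion("intentgap")),
    seed = seed,
    n_participants = config$n_participants,
    n_starters = config$n_starters,
    dk_count_behavior = config$dk_count_behavior,
    items_per_construct = config$items_per_construct,
    item_noise_sd = config$item_noise_sd,
    target_means = as.list(config$target_means),
    target_sds = as.list(config$target_sds),
    target_correlations = purrr::pmap(config$target_correlations, list),
    calibrated = !is.null(config$latent)
  ), path)
  invisible(path)
}
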