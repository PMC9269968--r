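#' Configuration of the synthetic cohort generator
#'
#' Collects every parameter of the generator: cohort composition, morphometric
#' distributions, the AR(1) sway dynamics and their coupling to body size, age
#' group and joint pain, the acceptability-mask Markov process, and the trial
#' protocol. Defaults emulate a mixed-breed clinical cohort standing on a
#' 67 Hz pressure mat: craniocaudal sway exceeds mediolateral sway, sway
#' magnitude scales with body length in adults, seniors sway more, and joint
#' pain adds high-frequency jitter (raising acceleration measures more than
#' extension measures, and more steeply when conscious proprioception is
#' abnormal).
#'
#' @param n_adults,n_seniors Cohort sizes (analysed study groups: 40 / 24).
#' @param weight_mean,weight_sd,height_mean,height_sd,length_mean,length_sd
#'   Morphometric distributions (kg, cm); defaults match the study cohort
#'   summaries.
#' @param morph_cor Common pairwise correlation between weight, height and
#'   length (the three are strongly collinear in dogs).
#' @param sigma_cc,sigma_ml Stationary SD of the slow sway component per axis
#'   in mm, for a reference-length adult.
#' @param phi_cc,phi_ml Pole positions of the slow component at `fs_hz`
#'   (values near 1 give the slow drift characteristic of quiet standing).
#' @param slow_poles 1 = AR(1) drift; 2 (default) = double-pole smooth drift,
#'   whose inertia-consistent spectrum keeps the drift out of the velocity
#'   and acceleration measures, as observed in pressure-mat recordings.
#' @param adjust_sd Stationary SD in mm (CC axis) of the mid-band
#'   postural-adjustment component: active corrective motion around 1-2 Hz
#'   riding on the slow drift. It contributes visibly to path length
#'   (velocity) but, sitting well below the tremor band, almost nothing to
#'   acceleration.
#' @param adjust_freq_hz,adjust_damping Resonance parameters of the
#'   adjustment component.
#' @param adjust_ml_ratio ML adjustment SD as a fraction of `adjust_sd`.
#' @param tremor_sd Stationary SD in mm of the narrowband fast component
#'   (postural tremor) on the CC axis. Because acceleration scales with the
#'   squared angular frequency of a narrowband motion, a few tenths of a mm
#'   of tremor near the filter edge carry most of the velocity and
#'   acceleration signal while barely moving the extension measures.
#' @param tremor_freq_hz Center frequency of the tremor resonance.
#' @param tremor_damping Pole radius of the tremor resonance in (0, 1);
#'   closer to 1 = narrower band.
#' @param tremor_ml_ratio ML tremor SD as a fraction of the CC tremor SD
#'   (craniocaudal tremor dominates in quadrupeds).
#' @param ref_length_cm Reference body length; per-dog sway SD scales as
#'   `(length / ref_length_cm)^size_alpha`.
#' @param size_alpha Size coupling exponent (positive: larger dogs sway more).
#' @param senior_gamma Senior sway multiplier (`>= 1`).
#' @param dog_sd Log-normal SD of the shared per-dog "overall swayiness"
#'   multiplier applied to both the slow drift and the tremor. This common
#'   factor is what makes all sway measures strongly correlated between dogs,
#'   as observed in real cohorts.
#' @param dog_sd_slow,dog_sd_fast Log-normal SDs of the channel-specific
#'   per-dog multipliers of the slow drift and the tremor, drawn independently
#'   of each other and of the shared factor.
#' @param pain_mu,pain_size Negative-binomial mean and size of senior total
#'   joint pain scores (adults are pain-free by eligibility).
#' @param pain_jitter_gain Extra tremor SD in mm per unit of total joint pain
#'   (pain perturbs fast corrective activity in the tremor band, loading the
#'   acceleration measures far more than the extension measures).
#' @param cp_abnormal_prob Probability a senior has abnormal conscious
#'   proprioception.
#' @param cp_interaction_gain Multiplier on the pain jitter when proprioception
#'   is abnormal (`> 1`: pain hurts balance more without proprioceptive
#'   feedback).
#' @param p_stay,p_recover Markov transition probabilities of the per-frame
#'   acceptability mask: P(acceptable -> acceptable) and P(unacceptable ->
#'   acceptable).
#' @param n_trials,frames_per_trial,fs_hz Trial protocol (10 trials of 8 s at
#'   67 frames/s).
#' @param stance_mm Four paw centers as a 4x2 matrix (ml, cc) in mm.
#' @param paw_sd_mm SD of the Gaussian paw pressure blobs.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_adults = 40, n_seniors = 24,
                         weight_mean = 21, weight_sd = 11,
                         height_mean = 51.5, height_sd = 14,
                         length_mean = 56.5, length_sd = 12.5,
                         morph_cor = 0.86,
                         sigma_cc = 4.3, sigma_ml = 3.0,
                         phi_cc = 0.97, phi_ml = 0.978,
                         slow_poles = 2,
                         adjust_sd = 1.0, adjust_freq_hz = 1.5,
                         adjust_damping = 0.85, adjust_ml_ratio = 0.6,
                         tremor_sd = 1.7, tremor_freq_hz = 4.5,
                         tremor_damping = 0.88, tremor_ml_ratio = 0.45,
                         ref_length_cm = 56.5, size_alpha = 1,
                         senior_gamma = 1.4, dog_sd = 0.3,
                         dog_sd_slow = 0.1, dog_sd_fast = 0.1,
                         pain_mu = 4.5, pain_size = 3,
                         pain_jitter_gain = 0.015,
                         cp_abnormal_prob = 0.375,
                         cp_interaction_gain = 2,
                         p_stay = 0.995, p_recover = 0.4,
                         n_trials = 10, frames_per_trial = 536, fs_hz = 67,
                         stance_mm = default_stance(), paw_sd_mm = 12,
                         seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(n_adults >= 0, n_seniors >= 0,
              sigma_cc > 0, sigma_ml > 0,
              phi_cc >= 0, phi_cc < 1, phi_ml >= 0, phi_ml < 1,
              adjust_sd >= 0, adjust_ml_ratio >= 0,
              adjust_freq_hz >= 0, adjust_freq_hz < fs_hz / 2,
              adjust_damping >= 0, adjust_damping < 1,
              tremor_sd >= 0, tremor_ml_ratio >= 0,
              tremor_freq_hz >= 0, tremor_freq_hz < fs_hz / 2,
              tremor_damping >= 0, tremor_damping < 1,
              senior_gamma >= 1, pain_jitter_gain >= 0,
              cp_abnormal_prob >= 0, cp_abnormal_prob <= 1,
              p_stay >= 0, p_stay <= 1, p_recover >= 0, p_recover <= 1,
              n_trials >= 1, frames_per_trial >= 1, fs_hz > 0,
              is.matrix(stance_mm), nrow(stance_mm) == 4, ncol(stance_mm) == 2)
  })
  structure(cfg, class = "synth_config")
}

#' @rdname synth_config
#' @export
default_stance <- function() {
  m <- rbind(front_left  = c(-70, 180),
             front_right = c( 70, 180),
             hind_left   = c(-70, -180),
             hind_right  = c( 70, -180))
  colnames(m) <- c("ml", "cc")
  m
}

# stationary AR(1) of length n with stationary SD sigma
ar1_series <- function(n, sigma, phi) {
  if (sigma == 0) return(rep(0, n))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sigma)
  eps <- rnorm(n - 1, 0, sigma * sqrt(1 - phi^2))
  for (t in seq_len(n - 1)) x[t + 1] <- phi * x[t] + eps[t]
  x
}

# resonant AR(2) (complex pole pair at freq_hz with radius damping), scaled
# to stationary SD sigma; burn-in reaches stationarity
ar2_resonance <- function(n, sigma, freq_hz, damping, fs) {
  if (sigma == 0) return(rep(0, n))
  a1 <- 2 * damping * cos(2 * pi * freq_hz / fs)
  a2 <- -damping^2
  # stationary variance of AR(2) with unit innovation variance
  g0 <- (1 - a2) / ((1 + a2) * (1 - a1 - a2) * (1 + a1 - a2))
  sigma_e <- sigma / sqrt(g0)
  burn <- ceiling(10 / (1 - damping))
  e <- rnorm(n + burn, 0, sigma_e)
  x <- as.numeric(stats::filter(e, c(a1, a2), method = "recursive"))
  x[(burn + 1):(burn + n)]
}

#' Simulate one COP segment (stationary AR(1) sway plus jitter)
#'
#' Per axis, a stationary AR(1) process (a discretized Ornstein-Uhlenbeck
#' sway model): `x[1] ~ N(0, sigma^2)`, `x[t+1] = phi * x[t] + e[t]` with
#' `e ~ N(0, sigma^2 (1 - phi^2))`, plus independent white jitter of SD
#' `jitter_sd` on every sample and, optionally, a narrowband tremor component
#' (resonant AR(2) at `tremor_freq_hz`). Axes are independent.
#'
#' @param sigma_cc,sigma_ml Stationary SDs in mm.
#' @param phi_cc,phi_ml AR(1) coefficients in `[0, 1)` (a single `phi` may be
#'   given via `phi_cc` with `phi_ml = phi_cc`).
#' @param jitter_sd White jitter SD in mm on the CC axis.
#' @param jitter_ml_ratio ML jitter SD as a fraction of `jitter_sd`.
#' @param slow_poles 1 for the plain AR(1) drift; 2 for a smooth drift with a
#'   double pole at `phi` (an inertia-consistent spectrum whose increments
#'   carry almost no energy in the tremor band).
#' @param tremor_sd Tremor SD in mm on the CC axis (0 = no tremor).
#' @param tremor_freq_hz,tremor_damping Tremor resonance parameters.
#' @param tremor_ml_ratio ML tremor SD as a fraction of `tremor_sd`.
#' @param n Number of samples.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed (local to this call).
#' @param dog_id,trial_id Ids carried into the output.
#' @return COP tibble with columns as in [extract_cop_series()].
#' @export
simulate_cop_segment <- function(sigma_cc, sigma_ml, phi_cc, phi_ml = phi_cc,
                                 jitter_sd = 0, jitter_ml_ratio = 1,
                                 adjust_sd = 0, adjust_freq_hz = 1.5,
                                 adjust_damping = 0.85, adjust_ml_ratio = 1,
                                 tremor_sd = 0, tremor_freq_hz = 4.5,
                                 tremor_damping = 0.92, tremor_ml_ratio = 1,
                                 slow_poles = 1, n = 536, fs = 67,
                                 seed = NULL, dog_id = NA_character_,
                                 trial_id = "t1") {
  stopifnot(sigma_cc >= 0, sigma_ml >= 0, jitter_sd >= 0, jitter_ml_ratio >= 0,
            tremor_sd >= 0, tremor_ml_ratio >= 0)
  if (phi_cc < 0 || phi_cc >= 1 || phi_ml < 0 || phi_ml >= 1) {
    abort("AR coefficients must lie in [0, 1)")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  white <- function(sigma) if (sigma == 0) rep(0, n) else rnorm(n, 0, sigma)
  slow <- function(sigma, phi) {
    if (slow_poles == 1) ar1_series(n, sigma, phi)
    else ar2_resonance(n, sigma, 0, phi, fs)
  }
  cc <- slow(sigma_cc, phi_cc) +
    ar2_resonance(n, adjust_sd, adjust_freq_hz, adjust_damping, fs) +
    ar2_resonance(n, tremor_sd, tremor_freq_hz, tremor_damping, fs) +
    white(jitter_sd)
  ml <- slow(sigma_ml, phi_ml) +
    ar2_resonance(n, adjust_sd * adjust_ml_ratio, adjust_freq_hz,
                  adjust_damping, fs) +
    ar2_resonance(n, tremor_sd * tremor_ml_ratio, tremor_freq_hz,
                  tremor_damping, fs) +
    white(jitter_sd * jitter_ml_ratio)
  tibble::tibble(dog_id = dog_id, trial_id = trial_id, frame = seq_len(n) - 1L,
                 ml_mm = ml, cc_mm = cc, valid = TRUE, fs_hz = fs)
}

#' Simulate per-frame acceptability masks
#'
#' Independent two-state Markov chains emulating intermittent acceptable
#' standing (the dog occasionally shifts, turns its head or steps). Chains
#' start from the stationary distribution.
#'
#' @param n_trials Number of trials.
#' @param length Frames per trial.
#' @param p_stay P(acceptable at t+1 | acceptable at t).
#' @param p_recover P(acceptable at t+1 | unacceptable at t).
#' @param seed Optional integer seed (local to this call).
#' @param trial_ids Optional trial id vector.
#' @return Tibble: `trial_id`, `frame_idx`, `acceptable`.
#' @export
simulate_masks <- function(n_trials, length, p_stay, p_recover, seed = NULL,
                           trial_ids = sprintf("t%02d", seq_len(n_trials))) {
  stopifnot(p_stay >= 0, p_stay <= 1, p_recover >= 0, p_recover <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p_acc <- if (p_recover + (1 - p_stay) > 0) {
    p_recover / (p_recover + (1 - p_stay))
  } else 1  # absorbing acceptable state
  purrr::map_dfr(trial_ids, function(tid) {
    flags <- logical(length)
    flags[1] <- runif(1) < p_acc
    u <- runif(length - 1)
    for (t in seq_len(length - 1)) {
      flags[t + 1] <- u[t] < (if (flags[t]) p_stay else p_recover)
    }
    tibble::tibble(trial_id = tid, frame_idx = seq_len(length) - 1L,
                   acceptable = flags)
  })
}

#' Render a COP series as synthetic pressure frames
#'
#' Distributes the dog's load over four isotropic Gaussian paw blobs. The
#' per-frame load fractions are the least-squares solution closest to equal
#' quarter loads subject to the pressure-weighted centroid matching the input
#' COP (non-negative, summing to 1), so [compute_cop()] recovers the input
#' trajectory to within half a sensel pitch. Total pressure per frame is
#' constant (`weight_kg` in arbitrary units).
#'
#' @param series COP tibble of one trial; coordinates must lie inside the
#'   convex hull of the paw centers (mat-frame coordinates; the stance is
#'   placed so all blobs are on the grid).
#' @param stance_mm 4x2 matrix of paw centers (ml, cc) in mm relative to the
#'   stance centroid.
#' @param weight_kg Total load.
#' @param pitch_mm Sensel pitch.
#' @param grid_shape `c(rows, cols)`; defaults to a grid covering the stance
#'   plus a 5-SD margin.
#' @param paw_sd_mm SD of each paw blob.
#' @return A [pressure_recording()].
#' @export
render_frames <- function(series, stance_mm = default_stance(), weight_kg = 20,
                          pitch_mm = 8.4, grid_shape = NULL, paw_sd_mm = 12) {
  margin <- 5 * paw_sd_mm
  offset_ml <- -min(stance_mm[, "ml"]) + margin
  offset_cc <- -min(stance_mm[, "cc"]) + margin
  paw_ml <- stance_mm[, "ml"] + offset_ml
  paw_cc <- stance_mm[, "cc"] + offset_cc
  if (is.null(grid_shape)) {
    grid_shape <- c(ceiling((max(paw_cc) + margin) / pitch_mm) + 1L,
                    ceiling((max(paw_ml) + margin) / pitch_mm) + 1L)
  }
  sens_ml <- (seq_len(grid_shape[2]) - 1) * pitch_mm
  sens_cc <- (seq_len(grid_shape[1]) - 1) * pitch_mm
  # per-paw pressure template (rows x cols), unit mass
  templates <- lapply(1:4, function(i) {
    g <- outer(exp(-(sens_cc - paw_cc[i])^2 / (2 * paw_sd_mm^2)),
               exp(-(sens_ml - paw_ml[i])^2 / (2 * paw_sd_mm^2)))
    g / sum(g)
  })
  tmpl_ml <- vapply(templates, function(g) sum(colSums(g) * sens_ml), numeric(1))
  tmpl_cc <- vapply(templates, function(g) sum(rowSums(g) * sens_cc), numeric(1))
  in_hull <- function(p, hull_ml, hull_cc) {
    # stance is a convex quadrilateral given in corner order FL, FR, HR, HL
    ord <- c(1, 2, 4, 3)
    hx <- hull_ml[ord]; hy <- hull_cc[ord]
    s <- sign((hx[c(2:4, 1)] - hx) * (p[2] - hy) - (hy[c(2:4, 1)] - hy) * (p[1] - hx))
    all(s >= 0) || all(s <= 0)
  }
  frames <- lapply(seq_len(nrow(series)), function(k) {
    target <- c(series$ml_mm[k] + offset_ml, series$cc_mm[k] + offset_cc)
    if (!in_hull(c(target[1], target[2]), paw_ml, paw_cc)) {
      abort(sprintf("frame %d: COP outside the stance hull", k - 1L))
    }
    w <- solve_loads(tmpl_ml, tmpl_cc, target)
    g <- Reduce(`+`, Map(`*`, templates, as.list(w)))
    g * weight_kg
  })
  pressure_recording(series$trial_id[1], frames, pitch_mm = pitch_mm,
                     fs_hz = series$fs_hz[1])
}

# loads w >= 0, sum(w) = 1, centroid constraint M w = target, closest to 1/4.
solve_loads <- function(xs, ys, target, tol = 1e-10) {
  M <- rbind(xs, ys, rep(1, 4))
  d <- c(target, 1)
  active <- rep(FALSE, 4)  # paws clamped to zero
  for (iter in 1:8) {
    free <- which(!active)
    Mf <- M[, free, drop = FALSE]
    base <- rep(0, 4); base[free] <- 1 / length(free)
    rhs <- d - M %*% base
    # minimum-norm correction within the free set
    corr <- tryCatch(
      crossprod(Mf, solve(tcrossprod(Mf), rhs)),
      error = function(e) abort("stance geometry degenerate; cannot solve loads"))
    w <- base; w[free] <- w[free] + as.numeric(corr)
    if (all(w >= -tol)) return(pmax(w, 0))
    active[which.min(w)] <- TRUE
    if (sum(!active) < 3) break
  }
  abort("COP not representable with non-negative paw loads")
}

#' Simulate a full synthetic cohort
#'
#' Draws per-dog morphometrics (correlated weight/height/length), ages from
#' the two study groups, joint-pain and proprioception status, per-dog sway
#' parameters (size-scaled, senior-inflated, pain-jittered), then per-trial
#' COP series and acceptability masks. Ground-truth per-dog parameters are
#' returned alongside, so tests can check parameter recovery.
#'
#' @param config A [synth_config()].
#' @return List with `dogs` (cohort tibble as in [read_cohort_table()] plus
#'   ground-truth columns `fls`, `sigma_cc_true`, `sigma_ml_true`,
#'   `jitter_sd_true`), `cop` (per-frame COP tibble across all dogs/trials),
#'   `masks` (acceptability tibble with `dog_id`), and `config`.
#' @export
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_adults + config$n_seniors
  senior <- rep(c(FALSE, TRUE), c(config$n_adults, config$n_seniors))
  mu <- c(config$weight_mean, config$height_mean, config$length_mean)
  sds <- c(config$weight_sd, config$height_sd, config$length_sd)
  R <- matrix(config$morph_cor, 3, 3); diag(R) <- 1
  Sigma <- R * tcrossprod(sds)
  draw_morph <- function(k) {
    m <- MASS::mvrnorm(k, mu, Sigma)
    bad <- m[, 1] <= 5.5 | m[, 2] <= 15 | m[, 3] <= 15  # eligibility + sanity
    while (any(bad)) {
      m[bad, ] <- MASS::mvrnorm(sum(bad), mu, Sigma)
      bad <- m[, 1] <= 5.5 | m[, 2] <= 15 | m[, 3] <= 15
    }
    m
  }
  morph <- draw_morph(n)
  lifespan <- estimate_lifespan(morph[, 2], morph[, 1])
  # adults: FLS uniform on (0.1, 0.72]; seniors: (0.78, 1.15)
  fls <- ifelse(senior, runif(n, 0.78, 1.15), runif(n, 0.1, 0.72))
  age <- pmax(fls * lifespan, 1.05)
  pain <- ifelse(senior, pmin(rnbinom(n, size = config$pain_size,
                                      mu = config$pain_mu), 64L), 0L)
  cp <- ifelse(senior & runif(n) < config$cp_abnormal_prob, "abnormal", "normal")
  size_fac <- (morph[, 3] / config$ref_length_cm)^config$size_alpha
  # one shared "overall swayiness" factor on both channels plus small
  # channel-specific factors; the shared factor dominates, so all metrics
  # correlate strongly between dogs while the senior (slow) and pain (fast)
  # effects stay channel-specific
  dog_fac_shared <- exp(rnorm(n, 0, config$dog_sd))
  dog_fac_slow <- dog_fac_shared * exp(rnorm(n, 0, config$dog_sd_slow))
  dog_fac_fast <- dog_fac_shared * exp(rnorm(n, 0, config$dog_sd_fast))
  group_fac <- ifelse(senior, config$senior_gamma, 1)
  sigma_cc_i <- config$sigma_cc * size_fac * dog_fac_slow * group_fac
  sigma_ml_i <- config$sigma_ml * size_fac * dog_fac_slow * group_fac
  adjust_i <- config$adjust_sd * size_fac * dog_fac_slow * group_fac
  tremor_i <- (config$tremor_sd + config$pain_jitter_gain * pain *
                 ifelse(cp == "abnormal", config$cp_interaction_gain, 1)) *
    size_fac * dog_fac_fast
  jitter_i <- rep(0, n)
  dogs <- tibble::tibble(
    dog_id = sprintf("dog%03d", seq_len(n)),
    age_years = age,
    weight_kg = morph[, 1],
    height_cm = morph[, 2],
    length_cm = morph[, 3],
    sex = sample(c("F", "M"), n, replace = TRUE),
    bcs = pmin(pmax(4L + rbinom(n, 3, 0.35) - 1L, 2L), 9L),
    total_joint_pain = as.integer(pain),
    cp_status = cp,
    cbpi_severity = ifelse(senior, round(pmin(pain * 0.3 +
      abs(rnorm(n, 0, 0.8)), 10), 1), NA_real_),
    cbpi_interference = ifelse(senior, round(pmin(pain * 0.25 +
      abs(rnorm(n, 0, 0.9)), 10), 1), NA_real_),
    load_score = ifelse(senior, round(pmin(4 + pain * 1.2 +
      abs(rnorm(n, 0, 4)), 52)), NA_real_),
    group = ifelse(senior, "B", "A"),
    fls = fls,
    sigma_cc_true = sigma_cc_i,
    sigma_ml_true = sigma_ml_i,
    tremor_sd_true = tremor_i,
    jitter_sd_true = jitter_i
  )
  cop <- purrr::map_dfr(seq_len(n), function(i) {
    purrr::map_dfr(seq_len(config$n_trials), function(j) {
      simulate_cop_segment(sigma_cc_i[i], sigma_ml_i[i],
                           phi_cc = config$phi_cc, phi_ml = config$phi_ml,
                           jitter_sd = jitter_i[i],
                           jitter_ml_ratio = config$tremor_ml_ratio,
                           adjust_sd = adjust_i[i],
                           adjust_freq_hz = config$adjust_freq_hz,
                           adjust_damping = config$adjust_damping,
                           adjust_ml_ratio = config$adjust_ml_ratio,
                           tremor_sd = tremor_i[i],
                           tremor_freq_hz = config$tremor_freq_hz,
                           tremor_damping = config$tremor_damping,
                           tremor_ml_ratio = config$tremor_ml_ratio,
                           slow_poles = config$slow_poles,
                           n = config$frames_per_trial,
                           fs = config$fs_hz, dog_id = dogs$dog_id[i],
                           trial_id = sprintf("t%02d", j))
    })
  })
  masks <- purrr::map_dfr(seq_len(n), function(i) {
    m <- simulate_masks(config$n_trials, config$frames_per_trial,
                        config$p_stay, config$p_recover)
    m$dog_id <- dogs$dog_id[i]
    m[c("dog_id", "trial_id", "frame_idx", "acceptable")]
  })
  list(dogs = dogs, cop = cop, masks = masks, config = config)
}
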