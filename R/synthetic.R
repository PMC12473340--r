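#' Configuration of the synthetic two-cohort calf study
#'
#' Defines the study conditions the simulator reproduces: cohort sizes, the
#' per-muscle macromolecular-fraction medians, the age contrasts on f and T1,
#' between-subject variability (split into an inflammation-like latent
#' component that raises T1 while lowering f, plus independent scatter),
#' smooth transmit-field (B1) and off-resonance (B0) ranges, and the
#' reference-image signal-to-noise ratio.
#'
#' All signal-affecting age contrasts are induced through the tissue
#' parameters (pool-size ratio and T1) only, so every index sees one
#' consistent ground truth.  The defaults place the young single-offset-scale
#' f between 0.070 (LG) and 0.075 (TA), the senior group 0.006 lower, and T1
#' at 1.40 s (young) versus 1.47 s (senior).
#'
#' @param n_young,n_senior cohort sizes (defaults 15 and 9).
#' @param f_young named per-muscle young-group median macromolecular fraction.
#' @param f_age_contrast young-minus-senior shift of f (applied to every
#'   muscle).
#' @param f_sd_latent,f_sd_indep,f_sd_muscle between-subject f standard
#'   deviation tied to the T1 latent, independent between-subject scatter,
#'   and per-muscle scatter.
#' @param t1_young,t1_senior group median T1 in seconds.
#' @param t1_sd_latent,t1_sd_indep,t1_sd_muscle T1 scatter components (s).
#' @param b1_range smooth relative-B1 field range.
#' @param b0_range_hz half-range of the smooth B0 field in Hz.
#' @param snr reference-image SNR (Rician noise level).
#' @param grid volume dimensions `c(nx, ny, nslices)`.
#' @param seed integer seed; mandatory, every phantom and acquisition draw
#'   derives from it deterministically.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_young = 15, n_senior = 9,
                          f_young = c(SOL = 0.071, MG = 0.072, LG = 0.070,
                                      TA = 0.075, TP = 0.074),
                          f_age_contrast = 0.006,
                          f_sd_latent = 0.0018, f_sd_indep = 0.0017,
                          f_sd_muscle = 0.001,
                          t1_young = 1.40, t1_senior = 1.47,
                          t1_sd_latent = 0.02, t1_sd_indep = 0.015,
                          t1_sd_muscle = 0.01,
                          b1_range = c(0.85, 1.15), b0_range_hz = 40,
                          snr = 100, grid = c(48, 48, 4), seed) {
  if (missing(seed)) stop("'seed' is mandatory in cohort_config()", call. = FALSE)
  gamma_check(seed, "seed")
  if (n_young < 2 || n_senior < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  if (any(f_young <= 0) || f_age_contrast < 0 || t1_young <= 0 || t1_senior <= 0)
    stop("tissue parameter medians must be positive", call. = FALSE)
  if (is.null(names(f_young)) || any(names(f_young) == ""))
    stop("f_young must be a named per-muscle vector", call. = FALSE)
  structure(list(n_young = n_young, n_senior = n_senior,
                 muscles = names(f_young), f_young = f_young,
                 f_age_contrast = f_age_contrast,
                 f_sd_latent = f_sd_latent, f_sd_indep = f_sd_indep,
                 f_sd_muscle = f_sd_muscle,
                 t1_young = t1_young, t1_senior = t1_senior,
                 t1_sd_latent = t1_sd_latent, t1_sd_indep = t1_sd_indep,
                 t1_sd_muscle = t1_sd_muscle,
                 b1_range = b1_range, b0_range_hz = b0_range_hz,
                 snr = snr, grid = grid, seed = as.integer(seed)),
            class = "cohort_config")
}

# elliptical cross-section labels shared by all slices; five calf muscles
leg_labels <- function(grid, muscles) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  x <- seq(-1, 1, length.out = nx); y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  ell <- function(cx, cy, a, b) ((X - cx) / a)^2 + ((Y - cy) / b)^2 <= 1
  geo <- list(SOL = c(0, -0.28, 0.50, 0.18),
              MG  = c(-0.35, -0.66, 0.22, 0.16),
              LG  = c(0.35, -0.66, 0.22, 0.16),
              TA  = c(0, 0.62, 0.28, 0.18),
              TP  = c(0, 0.15, 0.24, 0.15))
  lab2d <- matrix(0L, nx, ny)
  for (i in seq_along(muscles)) {
    g <- geo[[muscles[i]]]
    if (is.null(g)) stop("no geometry for muscle ", muscles[i], call. = FALSE)
    lab2d[ell(g[1], g[2], g[3], g[4])] <- i
  }
  array(rep(lab2d, nz), dim = c(nx, ny, nz))
}

# smooth low-order polynomial field scaled to [-1, 1] (max-normalised)
smooth_field <- function(grid, coefs) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  x <- seq(-1, 1, length.out = nx); y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  raw <- coefs[1] * X + coefs[2] * Y + coefs[3] * X * Y +
    coefs[4] * (X^2 - Y^2) + coefs[5] * (X^2 + Y^2 - 0.5)
  raw <- raw / max(abs(raw))
  array(rep(raw, nz), dim = c(nx, ny, nz))
}

#' Generate one synthetic calf cross-section phantom
#'
#' Deterministic given `(config$seed, subject_index, group)`: five
#' elliptical muscle regions on a slice stack, per-muscle two-pool tissue
#' truths drawn from the group's distributions (senior f shifted down, T1
#' up), and smooth polynomial B1 and B0 fields.  The free-pool T2 is tied to
#' T1 through `RA*T2A = 0.025` and the exchange parameters are held at the
#' muscle constants (`R*M0A = 48 /s`, `T2B = 6 us`, `RB = 1 /s`), so the
#' single-offset solve and the multi-offset fit see one consistent truth.
#'
#' @param config a [cohort_config()].
#' @param subject_index positive integer within the group.
#' @param group `"young"` or `"senior"`.
#' @return an object of class `leg_phantom`: `labels` (integer array),
#'   `truth` (per-muscle data frame), `b1`, `b0` (arrays), `m0`, `group`,
#'   `subject_index`, `config`.
#' @export
make_leg_phantom <- function(config, subject_index, group = c("young", "senior")) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must come from cohort_config()", call. = FALSE)
  group <- match.arg(group)
  gamma_check(subject_index, "subject_index")
  seed_s <- config$seed + 211L * as.integer(subject_index) +
    if (group == "senior") 104729L else 0L
  labels <- leg_labels(config$grid, config$muscles)
  senior <- group == "senior"
  draws <- with_seed(seed_s, {
    nm <- length(config$muscles)
    list(z = rnorm(1), e_f = rnorm(1), e_t1 = rnorm(1),
         e_fm = rnorm(nm), e_t1m = rnorm(nm),
         cb1 = runif(5, -1, 1), cb0 = runif(5, -1, 1))
  })
  f_med <- config$f_young - if (senior) config$f_age_contrast else 0
  t1_med <- if (senior) config$t1_senior else config$t1_young
  f <- pmax(f_med - config$f_sd_latent * draws$z +
              config$f_sd_indep * draws$e_f +
              config$f_sd_muscle * draws$e_fm, 1e-4)
  t1 <- pmax(t1_med + config$t1_sd_latent * draws$z +
               config$t1_sd_indep * draws$e_t1 +
               config$t1_sd_muscle * draws$e_t1m, 0.3)
  truth <- data.frame(muscle = config$muscles, label = seq_along(config$muscles),
                      f = unname(f), F = unname(f / (1 - f)),
                      t1 = unname(t1), ra = unname(1 / t1),
                      t2a = unname(0.025 * t1), t2b = 6e-6, rm0a = 48, rb = 1)
  mid <- mean(config$b1_range); half <- diff(config$b1_range) / 2
  b1 <- 1 + (mid - 1) + half * 0.95 * smooth_field(config$grid, draws$cb1)
  b0 <- config$b0_range_hz * 0.95 * smooth_field(config$grid, draws$cb0)
  structure(list(labels = labels, muscles = config$muscles, truth = truth,
                 b1 = b1, b0 = b0, m0 = 1000, group = group,
                 subject_index = subject_index, seed = seed_s,
                 config = config),
            class = "leg_phantom")
}

#' @export
print.leg_phantom <- function(x, ...) {
  cat(sprintf("synthetic calf phantom (%s subject %d): %s grid, %d muscles\n",
              x$group, x$subject_index,
              paste(dim(x$labels), collapse = "x"), nrow(x$truth)))
  print(x$truth[, c("muscle", "f", "t1")], row.names = FALSE)
  invisible(x)
}

#' Agarose phantom series preset
#'
#' Concentration series of nickel-doped agarose gels with theoretical
#' macromolecular fractions (fraction of agarose protons to total protons).
#' Agarose concentration sets the macromolecular pool while the nickel
#' doping sets T1; the default series is T1-matched (1.8 s throughout), the
#' usual practice so that MT differences across gels reflect agarose content
#' alone.
#'
#' @param concentrations percent agarose.
#' @param f_truth theoretical macromolecular fraction per concentration.
#' @param t1_s free-pool T1 per concentration in seconds.
#' @return an object of class `agarose_preset`.
#' @export
agarose_preset <- function(concentrations = c(0.5, 1, 2, 3, 4),
                           f_truth = c(0.002, 0.004, 0.009, 0.013, 0.017),
                           t1_s = rep(1.8, 5)) {
  if (length(concentrations) != length(f_truth) ||
      length(f_truth) != length(t1_s))
    stop("preset vectors must have equal length", call. = FALSE)
  if (is.unsorted(f_truth, strictly = TRUE))
    stop("f_truth must increase strictly with concentration", call. = FALSE)
  structure(list(concentrations = concentrations, f_truth = f_truth,
                 t1_s = t1_s),
            class = "agarose_preset")
}

# homogeneous cylinder phantom for one gel concentration
make_agarose_phantom <- function(f, t1, grid = c(32, 32, 2), seed = 1L,
                                 b1_range = c(0.85, 1.15), b0_range_hz = 20) {
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]
  x <- seq(-1, 1, length.out = nx); y <- seq(-1, 1, length.out = ny)
  X <- matrix(x, nx, ny); Y <- matrix(y, nx, ny, byrow = TRUE)
  lab2d <- matrix(0L, nx, ny); lab2d[X^2 + Y^2 <= 0.75^2] <- 1L
  labels <- array(rep(lab2d, nz), dim = grid)
  draws <- with_seed(seed, list(cb1 = runif(5, -1, 1), cb0 = runif(5, -1, 1)))
  mid <- mean(b1_range); half <- diff(b1_range) / 2
  b1 <- 1 + (mid - 1) + half * 0.95 * smooth_field(grid, draws$cb1)
  b0 <- b0_range_hz * 0.95 * smooth_field(grid, draws$cb0)
  truth <- data.frame(muscle = "GEL", label = 1L, f = f, F = f / (1 - f),
                      t1 = t1, ra = 1 / t1, t2a = 0.025 * t1, t2b = 6e-6,
                      rm0a = 48, rb = 1)
  structure(list(labels = labels, muscles = "GEL", truth = truth, b1 = b1,
                 b0 = b0, m0 = 1000, group = "phantom", subject_index = 1L,
                 seed = seed, config = NULL),
            class = "leg_phantom")
}

protocol_meta <- function(protocol) {
  row <- function(flip, off, dur, bw, tr, te, read, role)
    data.frame(mt_flip_deg = flip, mt_offset_hz = off, mt_duration_s = dur,
               mt_bandwidth_hz = bw, tr_s = tr, te_s = te,
               read_flip_deg = read, role = role,
               stringsAsFactors = FALSE)
  switch(protocol,
    multioffset = {
      offs <- c(1, 2, 5, 10, 20, 50, 100) * 1e3
      rbind(row(rep(c(350, 500), each = 7), rep(offs, 2), 0.01024, 200,
                0.05, 0.003, 6, "mt"),
            row(0, NA, NA, NA, 0.05, 0.003, 6, "reference"))
    },
    singleoffset = rbind(
      row(650, 1e3, 0.01024, 200, 0.05, 0.003, 6, "mt"),
      row(650, 1e5, 0.01024, 200, 0.05, 0.003, 6, "reference")),
    mtsat = rbind(
      row(0, NA, NA, NA, 0.05, 0.003, 4, "pdw"),
      row(500, 1.2e3, 0.009984, 375, 0.05, 0.003, 10, "mt"),
      row(0, NA, NA, NA, 0.05, 0.003, 20, "t1w")),
    vfa = row(0, NA, NA, NA, 0.025, 0.003, c(5, 15, 25), "vfa"),
    b0 = rbind(row(0, NA, NA, NA, 0.32, 4.92e-3, 15, "b0_echo1"),
               row(0, NA, NA, NA, 0.32, 7.38e-3, 15, "b0_echo2")),
    b1 = row(0, NA, NA, NA, NA, NA, NA, "b1"),
    stop("unknown protocol: ", protocol, call. = FALSE))
}

#' Simulate one acquisition protocol on a phantom
#'
#' Produces noiseless voxel signals from the two-pool and spoiled-gradient
#' -echo forward models, using each voxel's B1-scaled flip angles and
#' B0-shifted saturation offsets, then adds Rician noise at the requested
#' SNR.  Available protocols: `"multioffset"` (14 MT volumes + no-MT
#' reference), `"singleoffset"` (650 degrees at 1 and 100 kHz), `"mtsat"`
#' (PDw/MTw/T1w FLASH triplet), `"vfa"` (5/15/25 degrees, TR 25 ms), `"b0"`
#' (dual-echo phase pair) and `"b1"` (the relative transmit-field map).
#'
#' The SNR is defined on the mean of the protocol's reference volume inside
#' the labelled region; phase volumes get Gaussian phase noise `1/snr`; the
#' B1 map is passed through noise-free.
#'
#' @param phantom a [make_leg_phantom()] or agarose phantom.
#' @param protocol protocol name (above).
#' @param snr reference-image SNR; `Inf` for noiseless.  Defaults to the
#'   phantom's configured SNR (or 100).
#' @param seed integer seed for the noise draw.
#' @return an object of class `volume_stack`: `data` (4-D array), `meta`
#'   (per-volume acquisition table), `protocol`, `sigma`.
#' @export
simulate_protocol <- function(phantom, protocol, snr = NULL, seed = 1L) {
  if (!inherits(phantom, "leg_phantom"))
    stop("'phantom' must be a leg_phantom", call. = FALSE)
  protocol <- match.arg(protocol, c("multioffset", "singleoffset", "mtsat",
                                    "vfa", "b0", "b1"))
  if (is.null(snr))
    snr <- if (!is.null(phantom$config)) phantom$config$snr else 100
  meta <- protocol_meta(protocol)
  dims <- dim(phantom$labels)
  nvol <- nrow(meta)
  data <- array(0, dim = c(dims, nvol))
  idx_all <- which(phantom$labels > 0)

  if (protocol == "b1") {
    data[, , , 1] <- phantom$b1
    return(structure(list(data = data, meta = meta, protocol = protocol,
                          sigma = 0), class = "volume_stack"))
  }
  if (protocol == "b0") {
    wrap <- function(x) atan2(sin(x), cos(x))
    for (v in 1:2) {
      ph <- array(0, dims)
      ph[idx_all] <- wrap(2 * pi * phantom$b0[idx_all] * meta$te_s[v])
      data[, , , v] <- ph
    }
    sig <- if (is.finite(snr)) 1 / snr else 0
    if (sig > 0) data <- with_seed(seed, {
      for (v in 1:2) {
        ph <- data[, , , v]
        ph[idx_all] <- atan2(sin(ph[idx_all] + rnorm(length(idx_all), 0, sig)),
                             cos(ph[idx_all] + rnorm(length(idx_all), 0, sig)))
        data[, , , v] <- ph
      }
      data
    })
    return(structure(list(data = data, meta = meta, protocol = protocol,
                          sigma = sig), class = "volume_stack"))
  }

  for (m in seq_len(nrow(phantom$truth))) {
    tr_m <- phantom$truth[m, ]
    idx <- which(phantom$labels == tr_m$label)
    if (!length(idx)) next
    b1v <- phantom$b1[idx]; b0v <- phantom$b0[idx]
    for (v in seq_len(nvol)) {
      mv <- meta[v, ]
      sn <- 1
      if (mv$role == "mt" || (mv$role == "reference" && mv$mt_flip_deg > 0)) {
        p <- rf_pulse(mv$mt_flip_deg, mv$mt_offset_hz, mv$mt_duration_s,
                      mv$mt_bandwidth_hz, mv$tr_s)
        w1 <- omega1_cwpe(p) * b1v
        sn <- two_pool_sn(w1, mv$mt_offset_hz - b0v, tr_m$F, tr_m$rm0a,
                          tr_m$ra, tr_m$rb, tr_m$t2a, tr_m$t2b)
      }
      if (protocol == "mtsat" && mv$role == "mt") {
        # MT loss enters the FLASH steady state per TR, which is what the
        # saturation-index estimator inverts
        delta_v <- (mv$tr_s / tr_m$t1) * (1 / sn - 1)
        sig <- spgr_mt_signal(phantom$m0, tr_m$t1, mv$read_flip_deg * b1v,
                              mv$tr_s, delta_v)
      } else {
        # MT-prepared qMT volumes: normalized steady-state attenuation on a
        # low-flip readout
        sig <- spgr_signal(phantom$m0, tr_m$t1, mv$read_flip_deg * b1v,
                           mv$tr_s) * sn
      }
      vol <- data[, , , v]
      vol[idx] <- sig
      data[, , , v] <- vol
    }
  }
  ref_v <- which(meta$role == "reference")
  if (!length(ref_v)) ref_v <- which.max(apply(data, 4, function(a) mean(a[idx_all])))
  sigma <- if (is.finite(snr)) mean(data[, , , ref_v[1]][idx_all]) / snr else 0
  if (sigma > 0)
    data <- with_seed(seed, {
      out <- rician(data, sigma)
      dim(out) <- dim(data)
      out
    })
  structure(list(data = data, meta = meta, protocol = protocol, sigma = sigma),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("%s stack: %d volumes of %s (sigma = %.3g)\n", x$protocol,
              d[4], paste(d[1:3], collapse = "x"), x$sigma))
  invisible(x)
}

#' Simulate all protocols for one subject
#'
#' @param phantom a [make_leg_phantom()] phantom.
#' @param protocols protocols to simulate (see [simulate_protocol()]).
#' @param snr reference-image SNR (default: phantom config).
#' @param seed base seed; each protocol uses `seed + its index`.
#' @return named list of `volume_stack` objects.
#' @export
simulate_acquisitions <- function(phantom,
                                  protocols = c("singleoffset", "mtsat",
                                                "vfa", "b0", "b1"),
                                  snr = NULL, seed = NULL) {
  if (is.null(seed)) seed <- phantom$seed + 31L
  stacks <- lapply(seq_along(protocols), function(i)
    simulate_protocol(phantom, protocols[i], snr = snr, seed = seed + i))
  names(stacks) <- protocols
  stacks
}

#' Simulate a full two-cohort study
#'
#' @param config a [cohort_config()].
#' @param protocols protocols per subject.
#' @return a list of class `mt_cohort`: one element per subject with
#'   `id`, `group`, `phantom`, `stacks`.
#' @export
simulate_cohort <- function(config,
                            protocols = c("singleoffset", "mtsat", "vfa",
                                          "b0", "b1")) {
  subjects <- list()
  for (g in c("young", "senior")) {
    n <- if (g == "young") config$n_young else config$n_senior
    for (i in seq_len(n)) {
      ph <- make_leg_phantom(config, i, g)
      subjects[[length(subjects) + 1L]] <- list(
        id = sprintf("%s%02d", if (g == "young") "Y" else "S", i),
        group = g, phantom = ph,
        stacks = simulate_acquisitions(ph, protocols))
    }
  }
  structure(list(subjects = subjects, config = config, protocols = protocols),
            class = "mt_cohort")
}

#' Simulate the agarose concentration series
#'
#' One homogeneous-cylinder phantom per gel concentration with the preset's
#' theoretical macromolecular fraction mapped to the pool-size ratio
#' `F = f / (1 - f)`, all acquisition protocols simulated.
#'
#' @param preset an [agarose_preset()].
#' @param snr reference-image SNR (default 200).
#' @param seed integer seed.
#' @param protocols protocols to simulate per phantom.
#' @param grid phantom dimensions.
#' @return list of class `agarose_series`; per concentration: `concentration`,
#'   `f_truth`, `phantom`, `stacks`.
#' @export
make_agarose_series <- function(preset = agarose_preset(), snr = 200,
                                seed = 1L,
                                protocols = c("multioffset", "singleoffset",
                                              "mtsat", "vfa", "b0", "b1"),
                                grid = c(32, 32, 2)) {
  if (!inherits(preset, "agarose_preset"))
    stop("'preset' must come from agarose_preset()", call. = FALSE)
  # one scan session for the whole series: all gels share the B1/B0 field
  out <- lapply(seq_along(preset$concentrations), function(i) {
    ph <- make_agarose_phantom(preset$f_truth[i], preset$t1_s[i], grid,
                               seed = seed)
    stacks <- lapply(seq_along(protocols), function(j)
      simulate_protocol(ph, protocols[j], snr = snr, seed = seed + 100L * i + j))
    names(stacks) <- protocols
    list(concentration = preset$concentrations[i], f_truth = preset$f_truth[i],
         phantom = ph, stacks = stacks)
  })
  structure(out, class = "agarose_series", preset = preset)
}
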