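# Synthetic ground-truth generators: a layered, two-fold symmetric tetramer
# scaffold with rigid NTD dimers, LBD bodies, helix-G segments and anchor
# residues; planted splay/rotation motions with coordinate noise; particle
# classifications with a planted swapped fraction; and current sweeps with
# planted kinetics. Domains are rigid dummy point bodies (helical CA traces):
# enough structure for COM/axis/angle analyses, no physics.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# dummy CA helix: n residues along unit axis through center, canonical
# alpha-helix-like rise and radius
helix_trace <- function(n, center, axis, rise = 1.5, radius = 2.3,
                        phase = 0) {
  axis <- unit(axis)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(cross3(axis, ref))
  e2 <- cross3(axis, e1)
  s <- (seq_len(n) - (n + 1) / 2) * rise
  ang <- phase + seq_len(n) * 100 * pi / 180
  t(vapply(seq_len(n), function(i) {
    center + s[i] * axis + radius * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
  }, numeric(3)))
}

rotate_about_point <- function(coords, point, axis, theta_deg) {
  R <- rotation_matrix(axis, rad(theta_deg))
  sweep(sweep(coords, 2, point) %*% t(R), 2, point, "+")
}

default_scaffold_geometry <- function() {
  list(lbd_radius = 16, lbd_z = 18, n_res_lbd = 40,
       anchor_radius = 12, anchor_z = 30,
       helixg_offset = 9, helixg_z = 36, n_res_helixg = 11,
       ntd_radius = 10, ntd_z = 52, ntd_half_sep = 8,
       ntd_lobe_res = 12, ntd_z_spread = 5, hinge_z = 40)
}

#' Build the reference tetramer scaffold
#'
#' Four chains (A-D) arranged with a global two-fold symmetry axis along z:
#' each chain has a lower LBD body (a vertical dummy helix), an 11-residue
#' helix-G segment, and a single anchor residue marking the vertical
#' rotation axis; chains A+B and C+D contribute one NTD lobe each to the two
#' NTD dimers, whose local two-fold axes stand upright (parallel to z) in
#' the reference. Residue numbering per chain: LBD 1-40, helix G 50-60,
#' anchor 70, NTD lobe 101-112 and 121-132. A/C and B/D pairs are
#' distinguishable by chain label.
#'
#' The construction guarantees the geometric conventions the analyses rely
#' on: each NTD dimer's *second* principal axis runs along its local
#' two-fold axis, and the whole receptor's *first* principal axis runs along
#' z.
#'
#' @param geometry List of geometry parameters; see
#'   `confscape:::default_scaffold_geometry()` for the fields and defaults
#'   (all lengths in Angstrom).
#' @param model_id Model identifier.
#' @return A [structure_model()] carrying a `"scaffold"` attribute with the
#'   dimer/hinge/anchor annotations used by [apply_planted_motion()] and
#'   [scaffold_selections()].
#' @export
build_scaffold <- function(geometry = list(), model_id = "reference") {
  g <- utils::modifyList(default_scaffold_geometry(), geometry)
  if (g$lbd_radius <= 0 || g$ntd_radius <= 0 || g$anchor_radius <= 0) {
    stop("degenerate scaffold geometry: radii must be positive")
  }
  # build the A/B half explicitly; the C/D half is its exact image under the
  # global two-fold (180 degrees about z), so z is an exact principal axis
  # of the whole scaffold and of each NTD dimer
  chain_dirs <- list(A = unit(c(1, 1, 0)), B = unit(c(-1, 1, 0)))
  rows <- list()
  add_body <- function(chain, resno, coords) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, resid = "GLY", atom = "CA",
      x = coords[, 1], y = coords[, 2], z = coords[, 3],
      stringsAsFactors = FALSE)
  }
  anchors <- list()
  for (ch in names(chain_dirs)) {
    u <- chain_dirs[[ch]]
    tang <- cross3(c(0, 0, 1), u)
    lbd <- helix_trace(g$n_res_lbd, c(g$lbd_radius * u[1:2], g$lbd_z),
                       axis = c(0, 0, 1), rise = 0.5)
    add_body(ch, seq_len(g$n_res_lbd), lbd)
    anchor <- c(g$anchor_radius * u[1:2], g$anchor_z)
    anchors[[ch]] <- anchor
    hg_center <- anchor + c(g$helixg_offset * u[1:2], g$helixg_z - g$anchor_z)
    hg <- helix_trace(g$n_res_helixg, hg_center, axis = tang, rise = 1.5)
    add_body(ch, 50:60, hg)
    add_body(ch, 70L, rbind(anchor))
  }
  # NTD dimer "a" (chains A, B) centred on +y: each lobe is two x-axis
  # sub-helices at z +/- spread, so dimer variances order x > z > y and the
  # second principal axis is the (vertical) local two-fold axis; the partner
  # lobe is the two-fold image about the vertical axis through the dimer
  # centre
  center_a <- c(0, g$ntd_radius, g$ntd_z)
  dimers <- list(
    a = list(chains = c("A", "B"), center = center_a,
             outward = c(0, 1, 0), hinge = c(0, g$ntd_radius, g$hinge_z)),
    b = list(chains = c("C", "D"), center = c(0, -g$ntd_radius, g$ntd_z),
             outward = c(0, -1, 0), hinge = c(0, -g$ntd_radius, g$hinge_z)))
  lobe1 <- rbind(
    helix_trace(g$ntd_lobe_res, center_a + c(-g$ntd_half_sep, 0, g$ntd_z_spread),
                axis = c(1, 0, 0), rise = 1.5, radius = 2.0),
    helix_trace(g$ntd_lobe_res, center_a + c(-g$ntd_half_sep, 0, -g$ntd_z_spread),
                axis = c(1, 0, 0), rise = 1.5, radius = 2.0, phase = pi / 3))
  lobe2 <- rotate_about_point(lobe1, center_a, c(0, 0, 1), 180)
  resnos <- c(101:(100 + g$ntd_lobe_res), 121:(120 + g$ntd_lobe_res))
  add_body("A", resnos, lobe1)
  add_body("B", resnos, lobe2)
  half <- do.call(rbind, rows)
  other <- half
  other$chain <- c(A = "C", B = "D")[half$chain]
  flipped <- rotate_about_point(as.matrix(half[, c("x", "y", "z")]),
                                c(0, 0, 0), c(0, 0, 1), 180)
  other$x <- flipped[, 1]; other$y <- flipped[, 2]; other$z <- flipped[, 3]
  anchors$C <- rotate_about_point(rbind(anchors$A), c(0, 0, 0), c(0, 0, 1), 180)[1, ]
  anchors$D <- rotate_about_point(rbind(anchors$B), c(0, 0, 0), c(0, 0, 1), 180)[1, ]
  atoms <- rbind(half, other)
  model <- structure_model(model_id, atoms)
  attr(model, "scaffold") <- list(
    geometry = g, dimers = dimers, anchors = anchors,
    ntd_resno = range(c(101:(100 + g$ntd_lobe_res), 121:(120 + g$ntd_lobe_res))),
    lbd_resno = c(1L, 60L))
  model
}

#' Standard selections for the synthetic scaffold
#'
#' @param model A [build_scaffold()] output (annotations required).
#' @return Named list of [domain_selection()] objects: `dimer_a`, `dimer_b`,
#'   `helix_g`, `anchors`, and per-chain LBD selections.
#' @export
scaffold_selections <- function(model) {
  ann <- attr(model, "scaffold")
  if (is.null(ann)) stop("model has no scaffold annotations")
  ntd <- ann$ntd_resno
  dim_sel <- function(dname) {
    chains <- ann$dimers[[dname]]$chains
    domain_selection(paste0("dimer_", dname),
                     data.frame(chain = chains, res_start = ntd[1],
                                res_end = ntd[2], atom = "CA"),
                     role = "ntd_dimer")
  }
  chains <- names(ann$anchors)
  list(dimer_a = dim_sel("a"), dimer_b = dim_sel("b"),
       helix_g = domain_selection("helix_g",
                                  data.frame(chain = chains, res_start = 50,
                                             res_end = 60, atom = "CA"),
                                  role = "helix_g"),
       anchors = domain_selection("anchors",
                                  data.frame(chain = chains, res_start = 70,
                                             res_end = 70, atom = "CA"),
                                  role = "anchor_residue"))
}

#' Planted ground truth for the generators
#'
#' Defaults reflect the study conditions the generators emulate: upright
#' reference dimers (splay 0), resting A/C subunits with mobile B/D
#' subunits, a ~20% non-swapped particle population (swapped fraction 0.8)
#' with 5% label noise over triplicate classifications, and GluA1-like
#' kinetics (bi-exponential desensitization with tau_f = 4 ms, tau_s = 40
#' ms, fast-dominant amplitudes; recovery tau_rec = 192 ms).
#'
#' @param splay_a,splay_b NTD dimer tilt angles in degrees, [0, 180].
#' @param lbd_rotation Named per-chain LBD rotation angles (degrees) about
#'   the vertical anchor axis.
#' @param noise_sigma Isotropic coordinate noise SD (Angstrom).
#' @param swapped_fraction Probability that a particle is swapped.
#' @param label_noise Probability a particle is assigned uniformly at random
#'   over all classes, ignoring its category.
#' @param migration_noise Probability a particle leaves its stable preferred
#'   class within its category in a given run.
#' @param tau_f,tau_s,A_f,A_s Bi-exponential decay parameters (ms; relative
#'   amplitudes).
#' @param steady_state Steady-state current as a fraction of peak.
#' @param tau_rec Recovery time constant (ms).
#' @param r0 Recovery-curve intercept at zero interval.
#' @param depression Per-pulse multiplicative depression factor in a train.
#' @param peak_pA Conditioning-pulse peak current (pA, inward negative).
#' @param seed Integer seed recorded in every generated output.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(splay_a = 0, splay_b = 0,
                         lbd_rotation = c(A = 0, B = 0, C = 0, D = 0),
                         noise_sigma = 0,
                         swapped_fraction = 0.8, label_noise = 0.05,
                         migration_noise = 0.1,
                         tau_f = 4, tau_s = 40, A_f = 0.75, A_s = 0.25,
                         steady_state = 0.05, tau_rec = 192, r0 = 0.05,
                         depression = 0.8, peak_pA = -100, seed = 1L) {
  if (any(c(splay_a, splay_b) < 0) || any(c(splay_a, splay_b) > 180)) {
    stop("splay angles must lie in [0, 180] degrees")
  }
  if (any(lbd_rotation < 0) || any(lbd_rotation > 180)) {
    stop("LBD rotation angles must lie in [0, 180] degrees")
  }
  stopifnot(swapped_fraction >= 0, swapped_fraction <= 1,
            label_noise >= 0, label_noise <= 1,
            tau_f > 0, tau_s > 0, tau_rec > 0, noise_sigma >= 0,
            r0 >= 0, r0 < 1, depression > 0)
  structure(as.list(environment()), class = "ground_truth")
}

#' Apply planted rigid motions to the scaffold
#'
#' Rotates each NTD dimer by its planted tilt angle about its hinge point
#' (about the horizontal axis that tilts the dimer radially outward), rotates
#' each chain's LBD body (residues 1-60, i.e. LBD plus helix G) by its
#' planted angle about the vertical axis through that chain's anchor, then
#' adds isotropic Gaussian coordinate noise. The ground truth is recorded on
#' the result as attribute `"truth"`.
#'
#' @param reference A [build_scaffold()] output.
#' @param truth A [ground_truth()].
#' @param model_id Identifier of the new model.
#' @return A [structure_model()] with the same labels as the reference.
#' @export
apply_planted_motion <- function(reference, truth,
                                 model_id = paste0(reference$model_id, "_moved")) {
  ann <- attr(reference, "scaffold")
  if (is.null(ann)) stop("reference has no scaffold annotations")
  stopifnot(inherits(truth, "ground_truth"))
  atoms <- reference$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  splays <- c(a = truth$splay_a, b = truth$splay_b)
  for (dname in names(ann$dimers)) {
    d <- ann$dimers[[dname]]
    theta <- splays[[dname]]
    if (theta == 0) next
    axis <- unit(cross3(c(0, 0, 1), d$outward))
    idx <- atoms$chain %in% d$chains &
      atoms$resno >= ann$ntd_resno[1] & atoms$resno <= ann$ntd_resno[2]
    xyz[idx, ] <- rotate_about_point(xyz[idx, , drop = FALSE], d$hinge, axis, theta)
  }
  for (ch in names(truth$lbd_rotation)) {
    theta <- truth$lbd_rotation[[ch]]
    if (theta == 0) next
    if (!ch %in% names(ann$anchors)) stop("unknown chain '", ch, "' in lbd_rotation")
    idx <- atoms$chain == ch &
      atoms$resno >= ann$lbd_resno[1] & atoms$resno <= ann$lbd_resno[2]
    xyz[idx, ] <- rotate_about_point(xyz[idx, , drop = FALSE],
                                     ann$anchors[[ch]], c(0, 0, 1), theta)
  }
  if (truth$noise_sigma > 0) {
    set.seed(truth$seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, truth$noise_sigma),
                        ncol = 3L)
  }
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  out <- structure_model(model_id, atoms)
  attr(out, "scaffold") <- ann
  attr(out, "truth") <- truth
  out
}

#' Simulate an ensemble of conformers with planted motions
#'
#' Generates a reference scaffold plus `n_models` conformers whose splay
#' angles and B/D LBD rotations are planted on deterministic grids (splay
#' over `splay_range`, B/D rotations over `rotation_range`), with optional
#' coordinate noise. The planted parameters are returned as a table.
#'
#' @param n_models Number of conformers.
#' @param splay_range Length-2 range of planted splay angles (degrees).
#' @param rotation_range Length-2 range of planted B/D rotations (degrees).
#' @param noise_sigma Coordinate noise SD (Angstrom).
#' @param seed Integer seed.
#' @param geometry Scaffold geometry overrides.
#' @return List: `reference`, `models` (list of [structure_model()]),
#'   `truth` (data frame of planted parameters per model), `selections`.
#' @export
simulate_ensemble <- function(n_models = 12L, splay_range = c(0, 60),
                              rotation_range = c(0, 90), noise_sigma = 0.2,
                              seed = 1L, geometry = list()) {
  reference <- build_scaffold(geometry)
  grid <- seq(splay_range[1], splay_range[2], length.out = n_models)
  rot <- seq(rotation_range[1], rotation_range[2], length.out = n_models)
  set.seed(seed)
  model_seeds <- sample.int(.Machine$integer.max - 1L, n_models)
  truth_tbl <- data.frame(model_id = sprintf("model_%02d", seq_len(n_models)),
                          splay_a = grid, splay_b = rev(grid),
                          rot_B = rot, rot_D = rev(rot),
                          noise_sigma = noise_sigma, seed = model_seeds,
                          stringsAsFactors = FALSE)
  models <- lapply(seq_len(n_models), function(i) {
    tr <- ground_truth(splay_a = truth_tbl$splay_a[i],
                       splay_b = truth_tbl$splay_b[i],
                       lbd_rotation = c(A = 0, B = truth_tbl$rot_B[i],
                                        C = 0, D = truth_tbl$rot_D[i]),
                       noise_sigma = noise_sigma, seed = model_seeds[i])
    apply_planted_motion(reference, tr, model_id = truth_tbl$model_id[i])
  })
  list(reference = reference, models = models, truth = truth_tbl,
       selections = scaffold_selections(reference))
}

#' Simulate repeated particle classifications
#'
#' Draws each particle's true category once (swapped with probability
#' `swapped_fraction`), gives it a stable latent class preference within its
#' category (so that repeat runs co-migrate, as classifications of one
#' particle stack do), then for every requested class count k and replicate
#' assigns particles to classes: with probability `label_noise` uniformly
#' over all k classes, otherwise to a class of its own category (its
#' preferred class with probability 1 - `migration_noise`). Class counts per
#' category are proportional to the category fractions, which keeps the
#' measured fraction unbiased under label noise.
#'
#' @param n_particles Number of particles (shared across all runs).
#' @param truth A [ground_truth()] (uses `swapped_fraction`, `label_noise`,
#'   `migration_noise`).
#' @param k_list Class counts to sweep (each >= 3).
#' @param n_replicates Replicates per k (default 3).
#' @param seed Integer seed.
#' @return List of [classification_run()] objects with attribute `"truth"`
#'   recording the planted parameters and realized particle categories.
#' @export
simulate_classifications <- function(n_particles, truth, k_list = 6:20,
                                     n_replicates = 3L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), all(k_list >= 3L))
  if (any(k_list > n_particles)) stop("k exceeds the number of particles")
  set.seed(seed)
  particle_ids <- sprintf("p%07d", seq_len(n_particles))
  is_swapped <- stats::runif(n_particles) < truth$swapped_fraction
  latent <- stats::runif(n_particles)  # stable within-category preference
  run_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(k_list) * n_replicates)
  runs <- list()
  idx <- 0L
  for (k in k_list) {
    k_sw <- max(1L, min(k - 1L, round(k * truth$swapped_fraction)))
    k_ns <- k - k_sw
    class_ids <- sprintf("c%02d", seq_len(k))
    categories <- stats::setNames(
      c(rep("swapped", k_sw), rep("non_swapped", k_ns)), class_ids)
    sw_classes <- class_ids[seq_len(k_sw)]
    ns_classes <- class_ids[k_sw + seq_len(k_ns)]
    pref <- ifelse(is_swapped,
                   sw_classes[pmax(1L, pmin(k_sw, ceiling(latent * k_sw)))],
                   ns_classes[pmax(1L, pmin(k_ns, ceiling(latent * k_ns)))])
    for (rep_i in seq_len(n_replicates)) {
      idx <- idx + 1L
      set.seed(run_seeds[idx])
      assigned <- pref
      migrate <- stats::runif(n_particles) < truth$migration_noise
      if (any(migrate)) {
        assigned[migrate & is_swapped] <-
          sw_classes[sample.int(k_sw, sum(migrate & is_swapped), replace = TRUE)]
        assigned[migrate & !is_swapped] <-
          ns_classes[sample.int(k_ns, sum(migrate & !is_swapped), replace = TRUE)]
      }
      noisy <- stats::runif(n_particles) < truth$label_noise
      if (any(noisy)) {
        assigned[noisy] <- class_ids[sample.int(k, sum(noisy), replace = TRUE)]
      }
      runs[[idx]] <- classification_run(
        sprintf("k%02d_rep%d", k, rep_i),
        stats::setNames(assigned, particle_ids), categories)
    }
  }
  attr(runs, "truth") <- list(ground_truth = truth, seed = seed,
                              realized_swapped_fraction = mean(is_swapped))
  runs
}

# normalized decay shape, value 1 at t = 0
decay_shape <- function(t, truth) {
  af <- truth$A_f / (truth$A_f + truth$A_s)
  as_ <- truth$A_s / (truth$A_f + truth$A_s)
  (1 - truth$steady_state) *
    (af * exp(-t / truth$tau_f) + as_ * exp(-t / truth$tau_s)) +
    truth$steady_state
}

#' Simulate two-pulse recovery sweeps
#'
#' For each inter-pulse interval, builds one sweep: a conditioning agonist
#' pulse whose current rises instantaneously to the peak and decays
#' bi-exponentially to the steady state, followed (after the interval,
#' measured from conditioning offset) by a short test pulse whose peak is
#' scaled by the planted recovery curve 1 - (1 - r0) exp(-dt / tau_rec).
#' Additive Gaussian noise is scaled to the peak.
#'
#' @param truth A [ground_truth()].
#' @param intervals_ms Inter-pulse intervals (ms, from conditioning offset).
#' @param conditioning_ms,test_ms Pulse durations (ms).
#' @param sampling_khz Sampling rate (kHz).
#' @param noise_frac Gaussian noise SD as a fraction of the peak amplitude.
#' @param seed Integer seed.
#' @return List of [sweep_trace()] objects (one per interval), each with
#'   attributes `"interval_ms"` and `"truth"`.
#' @export
simulate_sweeps <- function(truth, intervals_ms = seq(20, 1000, by = 20),
                            conditioning_ms = 100, test_ms = 10,
                            sampling_khz = 5, noise_frac = 0, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), all(intervals_ms > 0))
  set.seed(seed)
  sweep_seeds <- sample.int(.Machine$integer.max - 1L, length(intervals_ms))
  dt <- 1 / sampling_khz
  on1 <- 10
  lapply(seq_along(intervals_ms), function(i) {
    gap <- intervals_ms[i]
    on2 <- on1 + conditioning_ms + gap
    t_end <- on2 + test_ms + 10
    time <- seq(0, t_end, by = dt)
    cur <- numeric(length(time))
    in1 <- time >= on1 & time < on1 + conditioning_ms
    cur[in1] <- truth$peak_pA * decay_shape(time[in1] - on1, truth)
    rec <- 1 - (1 - truth$r0) * exp(-gap / truth$tau_rec)
    in2 <- time >= on2 & time < on2 + test_ms
    cur[in2] <- truth$peak_pA * rec * decay_shape(time[in2] - on2, truth)
    if (noise_frac > 0) {
      set.seed(sweep_seeds[i])
      cur <- cur + stats::rnorm(length(cur), 0, noise_frac * abs(truth$peak_pA))
    }
    tr <- sweep_trace(time, cur,
                      data.frame(onset = c(on1, on2),
                                 duration = c(conditioning_ms, test_ms)))
    attr(tr, "interval_ms") <- gap
    attr(tr, "truth") <- truth
    tr
  })
}

#' Measure recovery ratios from two-pulse sweeps
#'
#' Peak currents (baseline-subtracted extrema) in the conditioning and test
#' pulse windows; ratio = second / first.
#'
#' @param sweeps Output of [simulate_sweeps()] (or equivalent list of
#'   two-pulse [sweep_trace()] objects with `"interval_ms"` attributes).
#' @return Data frame with columns `interval`, `ratio`.
#' @export
recovery_ratios <- function(sweeps) {
  rows <- lapply(sweeps, function(tr) {
    bl <- baseline_stats(tr)
    p1 <- find_peak(tr, tr$protocol$onset[1], tr$protocol$duration[1], bl$mean)
    p2 <- find_peak(tr, tr$protocol$onset[2], tr$protocol$duration[2], bl$mean)
    data.frame(interval = attr(tr, "interval_ms"),
               ratio = p2$value / p1$value)
  })
  do.call(rbind, rows)
}

#' Simulate a stimulus train with multiplicative depression
#'
#' Peak amplitudes follow a geometric sequence `peak * depression^(i-1)`;
#' each response decays with the fast time constant.
#'
#' @param truth A [ground_truth()].
#' @param n_pulses Number of pulses.
#' @param freq_hz Stimulation frequency (Hz).
#' @param pulse_ms Pulse duration (ms).
#' @param sampling_khz Sampling rate (kHz).
#' @param noise_frac Gaussian noise fraction of the first peak.
#' @param seed Integer seed.
#' @return A [sweep_trace()] with one protocol row per pulse.
#' @export
simulate_train <- function(truth, n_pulses = 5L, freq_hz = 20,
                           pulse_ms = 2, sampling_khz = 10,
                           noise_frac = 0, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), n_pulses >= 2L)
  period <- 1000 / freq_hz
  onsets <- 10 + period * (seq_len(n_pulses) - 1)
  time <- seq(0, max(onsets) + period, by = 1 / sampling_khz)
  cur <- numeric(length(time))
  for (i in seq_len(n_pulses)) {
    sel <- time >= onsets[i] & time < onsets[i] + pulse_ms
    cur[sel] <- truth$peak_pA * truth$depression^(i - 1) *
      exp(-(time[sel] - onsets[i]) / truth$tau_f)
  }
  if (noise_frac > 0) {
    set.seed(seed)
    cur <- cur + stats::rnorm(length(cur), 0, noise_frac * abs(truth$peak_pA))
  }
  tr <- sweep_trace(time, cur,
                    data.frame(onset = onsets, duration = pulse_ms))
  attr(tr, "truth") <- truth
  tr
}

#' Peak currents of a train sweep
#'
#' @param trace A [simulate_train()] output.
#' @return Numeric vector of baseline-subtracted peak currents (pA), one per
#'   protocol pulse.
#' @export
measure_train_peaks <- function(trace) {
  bl <- baseline_stats(trace)
  vapply(seq_len(nrow(trace$protocol)), function(i) {
    find_peak(trace, trace$protocol$onset[i], trace$protocol$duration[i],
              bl$mean)$value
  }, numeric(1))
}
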