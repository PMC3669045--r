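# Langevin (BAOAB) dynamics for toy systems, including a force-clamp mode
# that applies equal-and-opposite constant forces to the terminal atoms
# along the chain's initial end-to-end axis.  This produces trajectories
# for the rerun pipeline; it is deliberately not a production MD engine.

# Boltzmann constant, kJ mol^-1 K^-1
KB_KJMOL <- 0.00831446261815324

#' Toy force-clamp Langevin dynamics
#'
#' Integrates the system's potentials with the BAOAB splitting of Langevin
#' dynamics.  With `pull_force > 0`, constant forces `+F u` and `-F u` act
#' on the last and first atoms, where `u` is the unit vector from the first
#' to the last atom at the starting configuration — a desk-scale analog of
#' a force-clamp unfolding protocol.
#'
#' Stability: the harmonic stability bound is roughly
#' `dt < 2 / sqrt(k_max / m_min)`; for the bead-chain defaults
#' (k = 1000 kJ mol^-1 nm^-2, m = 50 amu) that is about 0.4 ps, and the
#' default `dt = 0.01` ps sits far below it.
#'
#' @param top a [topology()].
#' @param frame0 starting [frame()].
#' @param pull_force constant pull magnitude (kJ mol^-1 nm^-1); 0 disables.
#' @param n_steps number of integration steps.
#' @param dt time step (ps).
#' @param friction Langevin friction constant (ps^-1).
#' @param temperature bath temperature (K); 0 gives damped deterministic
#'   dynamics.
#' @param seed RNG seed; same seed, same trajectory.
#' @param cutoff nonbonded cutoff (nm) used during integration.
#' @param save_every save a frame every this many steps (frame 0 is always
#'   saved).
#' @param energy_max abort threshold: a potential energy above this raises
#'   an integration error naming the step.
#' @return list with `frames` (saved [frame()]s, times in ps),
#'   `kinetic` (kinetic energy at every step, kJ mol^-1), and
#'   `end_to_end` (first-to-last atom distance at every saved frame, nm).
#' @export
run_toy_forceclamp <- function(top, frame0, pull_force = 0,
                               n_steps = 1000, dt = 0.01, friction = 1,
                               temperature = 300, seed = 1,
                               cutoff = Inf, save_every = 10,
                               energy_max = 1e8) {
  check_frame_atoms(frame0, top)
  n <- n_atoms(top)
  m <- top$atoms$mass
  x <- frame0$coords
  v <- matrix(0, n, 3)
  u <- min_image(x[n, ], x[1, ], frame0$box)
  nu <- vec_norm(u)
  if (pull_force != 0 && nu == 0)
    stop_degenerate("coincident terminal atoms: pull direction undefined")
  if (nu > 0) u <- u / nu

  ext <- matrix(0, n, 3)
  if (pull_force != 0) {
    ext[n, ] <- pull_force * u
    ext[1, ] <- -pull_force * u
  }
  c1 <- exp(-friction * dt)
  c2 <- sqrt(pmax(0, 1 - c1^2)) * sqrt(KB_KJMOL * temperature / m)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  mkframe <- function(step) frame(x, time = step * dt, box = frame0$box)
  frames <- list(mkframe(0))
  kinetic <- numeric(n_steps)
  e2e <- vec_norm(min_image(x[n, ], x[1, ], frame0$box))

  f <- system_forces(top, mkframe(0), cutoff) + ext
  for (step in seq_len(n_steps)) {
    v <- v + (dt / 2) * f / m
    x <- x + (dt / 2) * v
    if (temperature > 0) {
      v <- c1 * v + c2 * matrix(stats::rnorm(3 * n), n, 3)
    } else {
      v <- c1 * v
    }
    x <- x + (dt / 2) * v
    fr <- mkframe(step)
    if (step %% 25 == 0 || step == n_steps || !all(is.finite(x))) {
      e <- if (all(is.finite(x))) system_energy(top, fr, cutoff) else Inf
      if (!is.finite(e) || e > energy_max)
        stop(errorCondition(
          sprintf("integration blew up at step %d (potential energy %g)",
                  step, e),
          class = c("pf_integration_error", "pf_error")))
    }
    f <- system_forces(top, fr, cutoff) + ext
    v <- v + (dt / 2) * f / m
    kinetic[step] <- 0.5 * sum(m * rowSums(v^2))
    if (step %% save_every == 0) {
      frames[[length(frames) + 1L]] <- fr
      e2e <- c(e2e, vec_norm(min_image(x[n, ], x[1, ], frame0$box)))
    }
  }
  list(frames = frames, kinetic = kinetic, end_to_end = e2e)
}
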