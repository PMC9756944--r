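# Configuration objects for the synthetic-data generators. Defaults are the
# study conditions the analyses assume: 30 ms PALM frames with a two-state
# (DNA-bound vs freely diffusing) mobility model, 10-min time-lapse frames,
# GC-rich genome with AT-enriched binding sites, and log-logistic growth.

#' Configuration for the two-state PALM simulator
#'
#' Molecules switch between a slow (DNA-bound) and a fast (freely diffusing)
#' Brownian state. The per-frame switch probabilities are
#' `switch_prob * (1 - f_slow)` out of the slow state and
#' `switch_prob * f_slow` out of the fast state, so the stationary slow-state
#' occupancy is exactly `f_slow` and `switch_prob` is a single overall
#' kinetic rate knob (the underlying study reports no switching kinetics).
#'
#' @param n_molecules number of molecules to simulate.
#' @param D_slow,D_fast diffusion coefficients (um^2/s) of the two states;
#'   defaults mirror the reported bound/free coefficients 0.015 and 0.400.
#' @param f_slow stationary fraction of molecules in the slow state.
#' @param switch_prob overall per-frame switching rate (see Details).
#' @param dt frame interval in seconds (30 ms camera exposure).
#' @param n_frames number of movie frames.
#' @param loc_sigma localization error SD per coordinate (um), applied i.i.d.
#'   after trajectory simulation.
#' @param p_bleach per-frame photobleaching probability (terminates a molecule).
#' @param p_blink per-frame blinking probability (removes single localizations).
#' @param fov field of view `c(width, height)` in um; trajectories reflect at
#'   the boundary.
#' @param stagger if `TRUE`, photoactivation times are uniform over the movie
#'   (realistic PALM density); if `FALSE` all molecules appear in frame 1.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return an object of class `spt_sim_config`.
#' @export
spt_sim_config <- function(n_molecules = 2000, D_slow = 0.015, D_fast = 0.400,
                           f_slow = 0.75, switch_prob = 0.05, dt = 0.03,
                           n_frames = 60, loc_sigma = 0.02, p_bleach = 0.1,
                           p_blink = 0.02, fov = c(30, 30), stagger = FALSE,
                           seed = NULL) {
  stop_if_not_count(n_molecules, "n_molecules")
  stop_if_not_count(n_frames, "n_frames", min = 2L)
  stop_if_not_pos(D_slow, "D_slow", strict = FALSE)
  stop_if_not_pos(D_fast, "D_fast", strict = FALSE)
  if (D_slow > D_fast) stop("`D_slow` must be <= `D_fast`", call. = FALSE)
  stop_if_not_prob(f_slow, "f_slow")
  stop_if_not_prob(switch_prob, "switch_prob")
  stop_if_not_prob(p_bleach, "p_bleach")
  stop_if_not_prob(p_blink, "p_blink")
  stop_if_not_pos(dt, "dt")
  stop_if_not_pos(loc_sigma, "loc_sigma", strict = FALSE)
  if (length(fov) != 2L) stop("`fov` must be c(width, height)", call. = FALSE)
  stop_if_not_pos(fov, "fov")
  structure(list(n_molecules = as.integer(n_molecules), D_slow = D_slow,
                 D_fast = D_fast, f_slow = f_slow, switch_prob = switch_prob,
                 dt = dt, n_frames = as.integer(n_frames),
                 loc_sigma = loc_sigma, p_bleach = p_bleach,
                 p_blink = p_blink, fov = as.numeric(fov),
                 stagger = isTRUE(stagger), seed = seed),
            class = c("spt_sim_config", "sim_config"))
}

#' Configuration for the hyphal time-lapse simulator
#'
#' Hyphae are 1D axes imaged every `frame_interval` minutes. The tip-proximal
#' chromosomal focus is anchored near the tip (`tip_focus_distance`), losing
#' anchorage at `tip_drift` um per frame when topoisomerase depletion is
#' emulated; further foci trail at `focus_spacing`. The tip-proximal focus
#' duplicates every `duplication_interval` frames and the sister pair
#' separates at `split_rate` um/min for the first 60 min, then plateaus.
#' Branches appear at `branch_prob` per frame and receive their first focus
#' `branch_focus_delay` minutes (+/- jitter) after emerging.
#'
#' @param n_hyphae number of (main) hyphae.
#' @param frame_interval acquisition interval in minutes.
#' @param n_frames frames per hypha.
#' @param extension_rate tip extension (um/frame).
#' @param branch_prob per-frame branching probability.
#' @param focus_spacing steady-state inter-focus spacing (um).
#' @param duplication_interval frames between tip-proximal duplications.
#' @param tip_drift anchorage-loss drift of the tip-proximal focus (um/frame).
#' @param stall_prob per-frame probability of permanent growth arrest.
#' @param pixel_size profile sampling (um/pixel).
#' @param peak_sigma Gaussian width of a focus in the intensity profile (um).
#' @param peak_amplitude focus amplitude (a.u.).
#' @param noise_sigma additive Gaussian profile noise SD (a.u.).
#' @param split_rate post-duplication sister separation rate (um/min).
#' @param branch_focus_delay median delay before a branch acquires its first
#'   focus (min).
#' @param tip_focus_distance initial tip-to-proximal-focus distance (um).
#' @param seed integer seed or `NULL`.
#' @return an object of class `hypha_sim_config`.
#' @export
hypha_sim_config <- function(n_hyphae = 50, frame_interval = 10, n_frames = 20,
                             extension_rate = 0.35, branch_prob = 0.02,
                             focus_spacing = 1.55, duplication_interval = 10,
                             tip_drift = 0, stall_prob = 0, pixel_size = 0.07,
                             peak_sigma = 0.15, peak_amplitude = 80,
                             noise_sigma = 8, split_rate = 1.75 / 60,
                             branch_focus_delay = 30, tip_focus_distance = 1.85,
                             seed = NULL) {
  stop_if_not_count(n_hyphae, "n_hyphae")
  stop_if_not_count(n_frames, "n_frames", min = 2L)
  stop_if_not_pos(frame_interval, "frame_interval")
  stop_if_not_pos(pixel_size, "pixel_size")
  stop_if_not_pos(c(peak_sigma, peak_amplitude, focus_spacing,
                    tip_focus_distance), "peak/spacing parameters")
  stop_if_not_pos(c(extension_rate, tip_drift, noise_sigma, split_rate,
                    branch_focus_delay), "rates", strict = FALSE)
  stop_if_not_prob(branch_prob, "branch_prob")
  stop_if_not_prob(stall_prob, "stall_prob")
  stop_if_not_count(duplication_interval, "duplication_interval")
  structure(list(n_hyphae = as.integer(n_hyphae),
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 extension_rate = extension_rate, branch_prob = branch_prob,
                 focus_spacing = focus_spacing,
                 duplication_interval = as.integer(duplication_interval),
                 tip_drift = tip_drift, stall_prob = stall_prob,
                 pixel_size = pixel_size, peak_sigma = peak_sigma,
                 peak_amplitude = peak_amplitude, noise_sigma = noise_sigma,
                 split_rate = split_rate,
                 branch_focus_delay = branch_focus_delay,
                 tip_focus_distance = tip_focus_distance, seed = seed),
            class = c("hypha_sim_config", "sim_config"))
}

#' Configuration for the differential ChIP simulator
#'
#' Generates a GC-rich genome with `n_sites` AT-boosted binding sites,
#' and per-sample fragment sets in two conditions with replicates. Counts are
#' negative-binomially overdispersed: each sample carries an i.i.d. gamma
#' multiplicative field with `block_size` bp correlation length (so window
#' counts at the analysis scale are NB with dispersion `dispersion`), and
#' enriched sites draw extra fragments with their own per-site gamma factor.
#'
#' @param genome_length genome size in bp.
#' @param gc_background background GC fraction (0.72 for *S. coelicolor*).
#' @param n_sites number of true binding sites.
#' @param site_width site width (bp).
#' @param site_at_boost AT fraction added inside sites.
#' @param enrichment_fold fold enrichment at sites, one value per condition
#'   (recycled across sites) or an `n_sites x n_conditions` matrix; must be
#'   >= 1 (1 = no enrichment).
#' @param fragment_length fragment length (bp).
#' @param library_sizes expected fragments per sample (scalar recycled, or one
#'   per sample in condition-major order).
#' @param dispersion NB dispersion phi at the window scale.
#' @param n_reps replicates per condition.
#' @param conditions condition labels (length 2 for a differential design).
#' @param block_size correlation length (bp) of the overdispersion field.
#' @param seed integer seed or `NULL`.
#' @return an object of class `chip_sim_config`.
#' @export
chip_sim_config <- function(genome_length = 5e5, gc_background = 0.72,
                            n_sites = 20, site_width = 100,
                            site_at_boost = 0.2, enrichment_fold = c(8, 1),
                            fragment_length = 150, library_sizes = 70000,
                            dispersion = 0.1, n_reps = 3,
                            conditions = c("depleted", "restored"),
                            block_size = 1000, seed = NULL) {
  stop_if_not_count(genome_length, "genome_length", min = 100L)
  stop_if_not_prob(gc_background, "gc_background")
  stop_if_not_count(n_sites, "n_sites", min = 0L)
  stop_if_not_count(site_width, "site_width")
  stop_if_not_pos(site_at_boost, "site_at_boost", strict = FALSE)
  stop_if_not_count(fragment_length, "fragment_length")
  stop_if_not_pos(library_sizes, "library_sizes")
  stop_if_not_pos(dispersion, "dispersion", strict = FALSE)
  stop_if_not_count(n_reps, "n_reps")
  stop_if_not_count(block_size, "block_size", min = 10L)
  if (n_sites * site_width >= genome_length) {
    stop("`n_sites * site_width` must be smaller than `genome_length`",
         call. = FALSE)
  }
  n_cond <- length(conditions)
  ef <- enrichment_fold
  if (is.matrix(ef)) {
    if (nrow(ef) != n_sites || ncol(ef) != n_cond) {
      stop("`enrichment_fold` matrix must be n_sites x n_conditions",
           call. = FALSE)
    }
  } else {
    if (length(ef) != n_cond) {
      stop("`enrichment_fold` must have one value per condition", call. = FALSE)
    }
    ef <- matrix(rep(ef, each = max(n_sites, 1L)), nrow = max(n_sites, 1L))
  }
  if (any(ef < 1)) stop("`enrichment_fold` must be >= 1 at sites", call. = FALSE)
  n_samples <- n_cond * n_reps
  lib <- rep_len(library_sizes, n_samples)
  structure(list(genome_length = as.integer(genome_length),
                 gc_background = gc_background, n_sites = as.integer(n_sites),
                 site_width = as.integer(site_width),
                 site_at_boost = site_at_boost, enrichment_fold = ef,
                 fragment_length = as.integer(fragment_length),
                 library_sizes = lib, dispersion = dispersion,
                 n_reps = as.integer(n_reps), conditions = conditions,
                 block_size = as.integer(block_size), seed = seed),
            class = c("chip_sim_config", "sim_config"))
}

#' Configuration for the growth-curve simulator
#'
#' OD follows the three-parameter log-logistic form
#' `d / (1 + exp(b * (log t - log e)))` plus Gaussian noise. The negative
#' `b_true` sign convention means an increasing curve; defaults mirror the
#' reported wild-type fit (relative slope -5.08, ED50 11.8 h).
#'
#' @param b_true relative slope (unitless; negative = increasing curve).
#' @param d_true plateau OD.
#' @param e_true ED50 in hours (time of half-maximal absorbance).
#' @param noise_sigma OD noise SD.
#' @param n_replicates replicate wells.
#' @param t_grid strictly increasing sampling times (h), all > 0
#'   (20-min Bioscreen sampling by default).
#' @param seed integer seed or `NULL`.
#' @return an object of class `growth_sim_config`.
#' @export
growth_sim_config <- function(b_true = -5.08, d_true = 1.0, e_true = 11.8,
                              noise_sigma = 0.02, n_replicates = 5,
                              t_grid = seq(1, 40, by = 1 / 3), seed = NULL) {
  stop_if_not_pos(d_true, "d_true")
  stop_if_not_pos(e_true, "e_true")
  stop_if_not_pos(noise_sigma, "noise_sigma", strict = FALSE)
  stop_if_not_count(n_replicates, "n_replicates")
  stop_if_not_pos(t_grid, "t_grid")
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("`t_grid` must be strictly increasing", call. = FALSE)
  }
  if (!is.finite(b_true)) stop("`b_true` must be finite", call. = FALSE)
  structure(list(b_true = b_true, d_true = d_true, e_true = e_true,
                 noise_sigma = noise_sigma,
                 n_replicates = as.integer(n_replicates),
                 t_grid = as.numeric(t_grid), seed = seed),
            class = c("growth_sim_config", "sim_config"))
}
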