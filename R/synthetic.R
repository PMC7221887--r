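# Synthetic paired diffusion-edited / conventional bucket matrices with
# known ground truth.  The generator emulates the contrast the method relies
# on: the training (diffusion-edited) matrix is dominated by broad
# macromolecular envelopes with sharp small-molecule peaks attenuated to a
# few percent, while the test (conventional) matrix carries the same broad
# components underneath full-amplitude sharp peaks.  All bucket values are
# obtained by integrating Gaussian peak shapes over each bucket interval, so
# sharp peaks narrower than a bucket are represented by their area.

# Integral of unit-area Gaussians over each bucket: one row per peak.
gauss_bucket_profiles <- function(grid, centers, sigmas) {
  edges <- grid$start_ppm + (0:grid$n_buckets) * grid$width
  t(vapply(seq_along(centers), function(p)
    diff(stats::pnorm(edges, mean = centers[p], sd = sigmas[p])),
    numeric(grid$n_buckets)))
}

#' Generate a broad macromolecule-like component spectrum
#'
#' A sum of broad Gaussian envelopes (sigma drawn from 0.05--0.3 ppm,
#' amplitudes drawn from 0.6--1.4) at fixed chemical-shift positions typical
#' of the component class: `lipid_like` at 0.9, 1.3, 2.0, 2.8, 4.2 and
#' 5.4 ppm (methyl/methylene chains, glycerol, unsaturated methine);
#' `collagen_like` at 1.0, 1.7, 2.3, 3.2, 3.9, 4.4 and 7.4 ppm (amino-acid
#' side chains plus the broad polypeptide backbone N-H region); `custom`
#' draws 4--8 random positions inside the grid.  The spectrum is bucketed by
#' exact Gaussian integration, non-negative, and returned at unit Euclidean
#' norm.  Bit-reproducible given `seed`.
#'
#' @param grid A [bucket_grid()].
#' @param kind `"lipid_like"`, `"collagen_like"` or `"custom"`.
#' @param seed Integer seed for the envelope widths/amplitudes.
#' @return Numeric unit-norm vector of length `grid$n_buckets`.
#' @export
make_macromolecule_spectrum <- function(grid,
                                        kind = c("lipid_like", "collagen_like",
                                                 "custom"),
                                        seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "bucket_grid"))
  with_seed(seed, {
    centers <- switch(kind,
      lipid_like = c(0.9, 1.3, 2.0, 2.8, 4.2, 5.4),
      collagen_like = c(1.0, 1.7, 2.3, 3.2, 3.9, 4.4, 7.4),
      custom = stats::runif(sample(4:8, 1L),
                            grid$start_ppm + 0.3, grid$end_ppm - 0.3))
    sig <- stats::runif(length(centers), 0.05, 0.3)
    amp <- stats::runif(length(centers), 0.6, 1.4)
    v <- as.vector(amp %*% gauss_bucket_profiles(grid, centers, sig))
    v / sqrt(sum(v^2))
  })
}

#' Generate paired training/test bucket matrices with known truth
#'
#' Builds a diffusion-edited-style training set and a conventional-style test
#' set on the same grid from `k_true` macromolecule component spectra
#' (lipid-like, collagen-like, then random custom envelopes):
#' each sample row is a log-normal(0, 0.5) non-negative mixture of the true
#' spectra plus sharp small-molecule Gaussian peaks
#' (sigma 0.005--0.02 ppm; heights heavy-tailed up to `sm_height_max` times
#' the maximum macromolecule intensity, so that, as in a real conventional
#' spectrum, a few dominant metabolite signals tower over the broad baseline
#' while most peaks are modest; amplitudes vary log-normally per sample),
#' scaled by a per-sample dilution factor and degraded with additive
#' Gaussian noise of standard deviation `noise_sigma` times the mean signal
#' (clamped at zero).
#' In the training set the sharp peaks are attenuated to `sm_attenuation`
#' (default 2%) of their conventional amplitude, emulating a pulsed-field-
#' gradient diffusion filter; the test set carries them at full amplitude.
#'
#' The master `seed` drives fixed per-stage streams (spectra, shared peak
#' positions, training draws, test draws), so the output is bit-reproducible
#' and the training set does not change when only `n_test` changes.
#'
#' @param n_train,n_test Numbers of training / test samples (default 82/800).
#' @param k_true Number of true components (<= 5; default 2).
#' @param noise_sigma Additive noise level as a fraction of the mean signal
#'   intensity (default 0.01).
#' @param n_small_molecule_peaks Number of shared sharp peaks (default 60,
#'   emulating the dense metabolite signal of a conventional spectrum).
#' @param sm_height_max Upper bound on sharp-peak height relative to the
#'   maximum macromolecule intensity (default 20).  Heights are drawn as
#'   `sm_height_max * u^4` with `u ~ uniform(0, 1)`: a heavy-tailed
#'   distribution whose largest draws approach the bound.
#' @param sm_attenuation Training-set attenuation of sharp peaks
#'   (default 0.02).
#' @param sm_variability Per-sample log-normal standard deviation of each
#'   sharp peak's amplitude (default 0.15): most small-molecule signals vary
#'   moderately around their typical level, so that dilution remains the
#'   dominant between-sample variation, the regime probabilistic quotient
#'   normalization assumes.
#' @param dilution_spread Per-sample dilution factors drawn log-uniformly
#'   from `[1/dilution_spread, dilution_spread]` (default 2).
#' @param grid Bucket grid (default [bucket_grid()], 154 buckets).
#' @param seed Master integer seed.
#' @return A list with `train` and `test` ([bucket_set()]s) and `truth`, an
#'   object of class `synthetic_truth` holding `true_spectra` (k x buckets,
#'   unit-norm rows), `component_kinds`, `true_A` (train mixing weights),
#'   `true_D` (test mixing weights), `dilution_train`, `dilution_test`,
#'   `noise_sigma`, `seed`, `small_molecule_params` (center, sigma, height
#'   scale) and `sm_bucket_max_train` / `sm_bucket_max_test` (per-sample
#'   maximum sharp-peak bucket intensity before noise).
#' @export
generate_paired_dataset <- function(n_train = 82L, n_test = 800L, k_true = 2L,
                                    noise_sigma = 0.01,
                                    n_small_molecule_peaks = 60L,
                                    sm_height_max = 20,
                                    sm_attenuation = 0.02,
                                    sm_variability = 0.15,
                                    dilution_spread = 2,
                                    grid = bucket_grid(), seed = 0L) {
  stopifnot(n_train >= 1, n_test >= 1, k_true >= 1, k_true <= 5,
            noise_sigma >= 0, n_small_molecule_peaks >= 0,
            sm_height_max >= 0, sm_attenuation >= 0, sm_variability >= 0,
            dilution_spread >= 1)
  kinds <- c("lipid_like", "collagen_like",
             rep("custom", max(0L, k_true - 2L)))[seq_len(k_true)]
  spectra <- t(vapply(seq_len(k_true), function(i)
    make_macromolecule_spectrum(grid, kinds[i], seed = seed + 11L * i),
    numeric(grid$n_buckets)))
  rownames(spectra) <- sprintf("Macro %d", seq_len(k_true))

  # shared sharp-peak positions/widths/height scales; heights are expressed
  # relative to the maximum macromolecule intensity (bucket value per unit
  # bucket width) of the mean component spectrum
  macro_height <- max(colMeans(spectra)) / grid$width
  sm <- with_seed(seed + 3L, {
    n_sm <- n_small_molecule_peaks
    if (n_sm > 0)
      data.frame(
        center = stats::runif(n_sm, grid$start_ppm + 0.1, grid$end_ppm - 0.1),
        sigma = stats::runif(n_sm, 0.005, 0.02),
        height = sm_height_max * macro_height * stats::runif(n_sm)^4)
    else data.frame(center = numeric(0), sigma = numeric(0),
                    height = numeric(0))
  })
  sm_profiles <- if (nrow(sm)) gauss_bucket_profiles(grid, sm$center, sm$sigma)
                 else matrix(0, 0L, grid$n_buckets)

  build <- function(n, stage_seed, attenuation, prefix) {
    with_seed(stage_seed, {
      W <- matrix(stats::rlnorm(n * k_true, 0, 0.5), n, k_true)
      dil <- exp(stats::runif(n, -log(dilution_spread), log(dilution_spread)))
      macro <- W %*% spectra
      if (nrow(sm)) {
        # per-sample, per-peak log-normal amplitude variation; a peak's bucket
        # contribution is its area: height * sigma * sqrt(2*pi)
        amp <- matrix(stats::rlnorm(n * nrow(sm), 0, sm_variability), n) *
          rep(sm$height * sm$sigma * sqrt(2 * pi), each = n) * attenuation
        sm_part <- amp %*% sm_profiles
      } else {
        amp <- matrix(0, n, 0)
        sm_part <- matrix(0, n, grid$n_buckets)
      }
      signal <- (macro + sm_part) * dil
      noise <- matrix(stats::rnorm(n * grid$n_buckets, 0,
                                   noise_sigma * mean(signal)),
                      n, grid$n_buckets)
      M <- pmax(signal + noise, 0)
      list(set = bucket_set(M, grid,
                            sample_ids = sprintf("%s_%03d", prefix, seq_len(n))),
           W = W, dil = dil,
           sm_max = if (nrow(sm)) apply(sm_part * dil, 1L, max)
                    else rep(0, n))
    })
  }
  tr <- build(n_train, seed + 1L, sm_attenuation, "train")
  te <- build(n_test, seed + 2L, 1, "test")
  truth <- structure(list(
    true_spectra = spectra, component_kinds = kinds,
    true_A = tr$W, true_D = te$W,
    dilution_train = tr$dil, dilution_test = te$dil,
    noise_sigma = noise_sigma, seed = as.integer(seed),
    small_molecule_params = sm,
    sm_bucket_max_train = tr$sm_max, sm_bucket_max_test = te$sm_max),
    class = "synthetic_truth")
  list(train = tr$set, test = te$set, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d components (%s); %d train / %d test samples; noise %.3g, seed %d\n",
    nrow(x$true_spectra), paste(x$component_kinds, collapse = ", "),
    nrow(x$true_A), nrow(x$true_D), x$noise_sigma, x$seed))
  invisible(x)
}
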