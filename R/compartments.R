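# Compartment parameter specifications for the placental phantom.
#
# Feature order is canonical throughout the package:
#   ADC, FA, AD, RD  in 1e-3 mm^2/s (FA unitless), T2* in ms.

PLACSEG_FEATURES <- c("ADC", "FA", "AD", "RD", "T2star")

#' Compartment parameter specification
#'
#' Describes the joint distribution of the five imaging features
#' (ADC, FA, AD, RD, T2*) inside one placental compartment, plus the
#' fraction of the placental volume it occupies. Diffusivities are in
#' 1e-3 mm^2/s, T2* in ms.
#'
#' @param name Compartment name, one of `"IVS"`, `"PV"`, `"PT"`, `"PL"`.
#' @param mean Named or ordered numeric vector of 5 feature means
#'   (ADC, FA, AD, RD, T2star).
#' @param sd Optional vector of 5 feature standard deviations; used to build
#'   a diagonal covariance when `cov` is not given.
#' @param cov Optional 5x5 symmetric positive-definite covariance matrix.
#' @param volume_fraction Fraction of placental voxels in this compartment.
#' @return An object of class `placseg_compartment`.
#' @export
compartment_spec <- function(name, mean, sd = NULL, cov = NULL,
                             volume_fraction = 0) {
  name <- match.arg(name, c("IVS", "PV", "PT", "PL", "brain"))
  mean <- as.numeric(mean)
  if (length(mean) != 5L)
    stop_placseg("compartment mean must have 5 features (ADC, FA, AD, RD, T2star)")
  names(mean) <- PLACSEG_FEATURES
  if (is.null(cov)) {
    if (is.null(sd)) stop_placseg("supply either sd or cov")
    if (length(sd) != 5L || any(sd <= 0))
      stop_placseg("sd must be 5 positive values")
    cov <- diag(as.numeric(sd)^2)
  }
  cov <- as.matrix(cov)
  dimnames(cov) <- list(PLACSEG_FEATURES, PLACSEG_FEATURES)
  if (!is_spd(cov))
    stop_placseg("compartment covariance for %s is not symmetric positive-definite", name)
  if (mean["FA"] < 0 || mean["FA"] > 1)
    stop_placseg("FA mean must lie in [0, 1]")
  if (any(mean[c("ADC", "AD", "RD", "T2star")] <= 0))
    stop_placseg("diffusivity and T2* means must be positive")
  if (volume_fraction < 0 || volume_fraction > 1)
    stop_placseg("volume_fraction must lie in [0, 1]")
  structure(list(name = name, mean = mean, cov = cov,
                 volume_fraction = volume_fraction),
            class = "placseg_compartment")
}

#' @export
print.placseg_compartment <- function(x, ...) {
  cat(sprintf("<compartment %s, fraction %.3f>\n", x$name, x$volume_fraction))
  print(round(x$mean, 3))
  invisible(x)
}

#' Default healthy placental compartments
#'
#' Three physiological compartments with distinct dual-contrast signatures:
#' intervillous space (maternal blood: high T2*, high near-isotropic
#' diffusivity), placental vessels (coherent flow: high FA), and placental
#' tissue (villous parenchyma: lower T2* and diffusivity). T2* means are
#' given at the reference gestational age `ga_ref` and shifted linearly by
#' `t2s_shift` (ms), e.g. by a cohort's gestational-age trend.
#'
#' @param t2s_shift Named numeric shift (ms) added to each compartment's
#'   T2* mean, default zeros.
#' @param fractions Volume fractions for IVS, PV, PT; must sum to 1.
#' @return Named list of [compartment_spec()] objects.
#' @export
healthy_compartments <- function(t2s_shift = c(IVS = 0, PV = 0, PT = 0),
                                 fractions = c(IVS = 0.35, PV = 0.20, PT = 0.45)) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_placseg("compartment volume fractions must sum to 1")
  sh <- c(IVS = 0, PV = 0, PT = 0)
  sh[names(t2s_shift)] <- t2s_shift
  list(
    IVS = compartment_spec("IVS",
      mean = c(2.80, 0.15, 3.10, 2.65, 100 + sh[["IVS"]]),
      sd   = c(0.25, 0.05, 0.30, 0.25, 8),
      volume_fraction = fractions[["IVS"]]),
    PV = compartment_spec("PV",
      mean = c(1.70, 0.45, 2.40, 1.35, 75 + sh[["PV"]]),
      sd   = c(0.25, 0.07, 0.30, 0.25, 7),
      volume_fraction = fractions[["PV"]]),
    PT = compartment_spec("PT",
      mean = c(1.40, 0.20, 1.60, 1.30, 55 + sh[["PT"]]),
      sd   = c(0.20, 0.05, 0.25, 0.20, 6),
      volume_fraction = fractions[["PT"]])
  )
}

#' Lesion parameter presets
#'
#' Representative (mean, SD) feature quintuples for five placental lesion
#' phenotypes observed in complicated pregnancies: subchorionic
#' fibrin/intervillous thrombus (`case1`), focal villous edema (`case2`),
#' intervillous thrombohematoma (`case3`), chorionitis with fetal
#' inflammatory response (`case4`) and anemia-associated placentomegaly with
#' increased extracellular diffusion (`case5`).
#'
#' @param case One of `"case1"` ... `"case5"`.
#' @param volume_fraction Fraction of placental voxels occupied by the lesion.
#' @return A [compartment_spec()] with name `"PL"`.
#' @export
lesion_preset <- function(case = "case4", volume_fraction = 0.15) {
  tab <- list(
    #        ADC    FA    AD    RD   T2*        SDs
    case1 = list(m = c(1.43, 0.27, 1.67, 1.33, 44.2),
                 s = c(0.28, 0.06, 0.80, 0.26, 9.9)),
    case2 = list(m = c(2.29, 0.21, 2.43, 2.22, 60.6),
                 s = c(0.34, 0.05, 0.93, 0.22, 9.4)),
    case3 = list(m = c(2.12, 0.22, 2.41, 2.35, 61.4),
                 s = c(0.31, 0.04, 0.67, 0.26, 14.0)),
    case4 = list(m = c(1.26, 0.49, 2.01, 1.01, 32.9),
                 s = c(0.12, 0.07, 0.51, 0.15, 5.4)),
    case5 = list(m = c(2.98, 0.43, 3.93, 1.95, 33.6),
                 s = c(0.17, 0.06, 0.61, 0.17, 6.7))
  )
  case <- match.arg(case, names(tab))
  compartment_spec("PL", mean = tab[[case]]$m, sd = tab[[case]]$s,
                   volume_fraction = volume_fraction)
}

# Eigenvalue triple (AD, RD + delta, RD - delta) with delta chosen so the
# tensor's FA equals the drawn FA; the triple is then sorted descending, so
# the realized axial/radial diffusivities are the sorted-eigenvalue
# definitions (they deviate from the drawn AD/RD only in the marginal case
# where the FA-matching split lifts lambda2 above AD). Infeasible when the
# drawn FA is below the lambda2 = lambda3 minimum, a tail eigenvalue would
# go negative, or AD < RD.
tensor_eigs_from_features <- function(fa, ad, rd) {
  lbar <- (ad + 2 * rd) / 3
  A <- (ad - lbar)^2 + 2 * (rd - lbar)^2
  B <- ad^2 + 2 * rd^2
  a <- (2 / 3) * fa^2
  d2 <- (a * B - A) / (2 * (1 - a))
  delta <- sqrt(pmax(d2, 0))
  ok <- is.finite(d2) & d2 >= 0 & a < 1 & (rd - delta) >= 0 & ad >= rd
  delta[!ok] <- NA_real_
  l1 <- pmax(ad, rd + delta)
  l2 <- pmin(ad, rd + delta)
  list(l1 = l1, l2 = l2, l3 = rd - delta, feasible = ok)
}

# Draw n feature vectors from a compartment's Gaussian, rejecting draws that
# cannot be realized as a physical diffusion tensor, and recomputing ADC as
# (AD + 2 RD)/3 (the drawn ADC is discarded; a draw whose ADC disagrees with
# the implied value by more than adc_tol is also rejected). Returns the
# realized feature matrix and the tensor eigenvalues. Caller owns the RNG.
draw_compartment_features <- function(spec, n, adc_tol = 0.15,
                                      max_redraw = 100L) {
  if (n == 0L) {
    return(list(features = matrix(numeric(0), 0, 5,
                                  dimnames = list(NULL, PLACSEG_FEATURES)),
                eigs = matrix(numeric(0), 0, 3)))
  }
  feat <- matrix(NA_real_, n, 5, dimnames = list(NULL, PLACSEG_FEATURES))
  eigs <- matrix(NA_real_, n, 3)
  need <- rep(TRUE, n)
  total_redraws <- 0L
  for (round in seq_len(max_redraw)) {
    m <- sum(need)
    if (m == 0L) break
    x <- MASS::mvrnorm(m, mu = spec$mean, Sigma = spec$cov)
    x <- matrix(x, ncol = 5)
    fa <- x[, 2]; ad <- x[, 3]; rd <- x[, 4]; t2s <- x[, 5]
    te <- tensor_eigs_from_features(fa, ad, rd)
    adc_impl <- (ad + 2 * rd) / 3
    ok <- te$feasible & fa > 0.005 & fa < 0.99 & rd > 0 & t2s > 1 &
      abs(x[, 1] - adc_impl) <= adc_tol * adc_impl
    idx <- which(need)[ok]
    if (length(idx)) {
      # realized AD/RD come from the sorted eigenvalues, so a perfect
      # tensor fit reproduces the recorded truth exactly
      feat[idx, ] <- cbind(adc_impl[ok], fa[ok], te$l1[ok],
                           (te$l2[ok] + te$l3[ok]) / 2, t2s[ok])
      eigs[idx, ] <- cbind(te$l1[ok], te$l2[ok], te$l3[ok])
      need[idx] <- FALSE
    }
    total_redraws <- total_redraws + sum(!ok)
  }
  if (any(need))
    stop_placseg("compartment %s: %d voxels still infeasible after %d re-draw rounds",
                 spec$name, sum(need), max_redraw)
  if (total_redraws > 0)
    warn_placseg("compartment %s: re-drew %d infeasible feature vectors",
                 spec$name, total_redraws)
  list(features = feat, eigs = eigs)
}
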