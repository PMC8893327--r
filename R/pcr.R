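#' Droplet digital PCR concentration by Poisson statistics
#'
#' The mean copies per droplet is `lambda = -ln((N - Npos) / N)` and the
#' concentration is `dilution * lambda / dropletVolume`. The 95% CI is the
#' binomial-delta interval on the negative-droplet fraction pushed through
#' the log: `lambda_{lo,hi} = -ln(p +/- 1.96 * sqrt(p (1 - p) / N))` with
#' `p = (N - Npos) / N`, clipped to the valid range. Wells with fewer than
#' 10,000 droplets are rejected (too few partitions for a stable Poisson
#' estimate); saturated wells (all droplets positive) are flagged with an
#' undefined concentration.
#'
#' @param nDroplets total accepted droplets N (>= 10,000)
#' @param nPositive positive droplets
#' @param dropletVolume droplet volume in uL (instrument-specific; no
#'   default)
#' @param dilution template dilution factor
#' @return list with `lambda`, `concentration` (copies/uL), `ci`
#'   (concentration scale), `lambdaCi`, `saturated`
#' @export
ddpcrConcentration <- function(nDroplets, nPositive, dropletVolume,
                               dilution = 1) {
  stopifnot(nPositive >= 0, nPositive <= nDroplets, dropletVolume > 0)
  if (nDroplets < 10000)
    stop("well rejected: fewer than 10,000 droplets")
  if (nPositive == nDroplets)
    return(list(lambda = NA_real_, concentration = NA_real_,
                ci = c(NA_real_, NA_real_),
                lambdaCi = c(NA_real_, NA_real_), saturated = TRUE))
  p <- (nDroplets - nPositive) / nDroplets
  lambda <- -log(p)
  se <- sqrt(p * (1 - p) / nDroplets)
  pLo <- min(1, p + 1.96 * se)   # more negatives -> lower lambda
  pHi <- max(1e-12, p - 1.96 * se)
  lambdaCi <- c(-log(pLo), -log(pHi))
  k <- dilution / dropletVolume
  list(lambda = lambda, concentration = k * lambda, ci = k * lambdaCi,
       lambdaCi = lambdaCi, saturated = FALSE)
}

#' TE copies per genome from ddPCR concentrations
#'
#' Divides the TE concentration by half of the Rp49 (single-copy diploid
#' normalizer) concentration: `copies = te / (rp49 / 2)`. Confidence
#' intervals, when both inputs carry them, are propagated to first order by
#' summing relative half-widths in quadrature.
#'
#' @param te,rp49 concentrations as numbers or results of
#'   [ddpcrConcentration]
#' @return list with `copies` and (when available) `ci`
#' @export
copiesPerGenome <- function(te, rp49) {
  getVal <- function(x) if (is.list(x)) x$concentration else x
  getCi <- function(x) if (is.list(x)) x$ci else c(NA_real_, NA_real_)
  teV <- getVal(te); rpV <- getVal(rp49)
  if (is.na(rpV) || rpV <= 0) stop("Rp49 concentration must be positive")
  copies <- teV / (rpV / 2)
  teCi <- getCi(te); rpCi <- getCi(rp49)
  if (anyNA(c(teCi, rpCi))) return(list(copies = copies,
                                        ci = c(NA_real_, NA_real_)))
  relTe <- (teCi[2] - teCi[1]) / 2 / teV
  relRp <- (rpCi[2] - rpCi[1]) / 2 / rpV
  rel <- sqrt(relTe^2 + relRp^2)
  list(copies = copies, ci = copies * c(1 - rel, 1 + rel))
}

#' qPCR fold change by the 2^-ddCt method with propagated SD
#'
#' Per condition, `dCt = mean(Ct_target) - mean(Ct_housekeeping)` over the
#' replicate wells; `ddCt = dCt_experiment - dCt_control` and the fold
#' change is `2^-ddCt`. Replicate SDs are converted to SDs of the mean
#' (SD / sqrt(nrep)) and propagated in quadrature through both dCt terms;
#' the fold interval reported is `[2^(-ddCt - SD), 2^(-ddCt + SD)]`.
#'
#' @param panel data.frame with columns `condition`, `gene`, `ct`
#'   (replicate wells as rows)
#' @param experiment,control condition labels
#' @param target target gene label
#' @param housekeeping housekeeping gene label (default `"Rp49"`)
#' @return list with `fold`, `ddCt`, `sd` (of ddCt) and `foldInterval`
#' @export
ddctFold <- function(panel, experiment, control, target,
                     housekeeping = "Rp49") {
  need <- expand.grid(condition = c(experiment, control),
                      gene = c(target, housekeeping),
                      stringsAsFactors = FALSE)
  grab <- function(cond, gene) {
    ct <- panel$ct[panel$condition == cond & panel$gene == gene]
    if (length(ct) < 3L)
      stop("missing replicates for ", gene, " in ", cond)
    if (any(ct <= 0)) stop("Ct values must be positive")
    ct
  }
  invisible(Map(grab, need$condition, need$gene))  # validate all four cells
  dct <- function(cond) {
    t <- grab(cond, target); h <- grab(cond, housekeeping)
    list(d = mean(t) - mean(h),
         var = sd(t)^2 / length(t) + sd(h)^2 / length(h))
  }
  e <- dct(experiment); c0 <- dct(control)
  ddct <- e$d - c0$d
  sdd <- sqrt(e$var + c0$var)
  list(fold = 2^(-ddct), ddCt = ddct, sd = sdd,
       foldInterval = c(2^(-ddct - sdd), 2^(-ddct + sdd)))
}

#' Simulate a ddPCR well by Poisson droplet occupancy
#'
#' Given a true template concentration, droplets are occupied independently
#' with probability `1 - exp(-lambda)`; the positive-droplet count is
#' binomial. Useful for validating estimator calibration against a known
#' truth.
#'
#' @param lambda true mean copies per droplet
#' @param nDroplets droplets generated
#' @param seed RNG seed
#' @return list with `nDroplets` and `nPositive`
#' @export
simulateDdpcrWell <- function(lambda, nDroplets = 15000L, seed = 1L) {
  stopifnot(lambda >= 0)
  set.seed(seed)
  list(nDroplets = nDroplets,
       nPositive = rbinom(1L, nDroplets, 1 - exp(-lambda)))
}
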