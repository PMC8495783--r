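# Maximum-likelihood fitting for the built-in engine.

#' Fit a codon model by maximum likelihood
#'
#' Optimizes kappa and one omega per rate class (M0: the single background
#' class; branch model: background plus one class per label token on the
#' tree) by bounded quasi-Newton (L-BFGS-B) on log-transformed parameters,
#' with box constraints kappa in \[0.01, 50\] and omega in \[1e-4, 20\].
#' Branch lengths are fixed from the input tree, so `np = 1 + #classes`.
#' A non-finite likelihood at the requested start triggers one retry from
#' the fallback start (kappa = 2, omega = 0.5).
#'
#' @param aln a [CodonAlignment-class].
#' @param phylogeny a [Phylogeny-class] with branch lengths (labels define
#'   the classes when `model = "branch"`).
#' @param model `"M0"` (single omega, labels ignored) or `"branch"` (one
#'   omega per label token plus background).
#' @param startOmega starting omega for every class.
#' @param startKappa starting kappa.
#' @param codonFreqs equilibrium codon frequencies (default equal).
#' @return an [EngineFit-class].
#' @export
fitCodonModel <- function(aln, phylogeny, model = c("M0", "branch"),
                          startOmega = 0.5, startKappa = 2,
                          codonFreqs = rep(1 / 61, 61)) {
  model <- match.arg(model)
  phyUse <- phylogeny
  if (model == "M0" && any(nzchar(phylogeny@labels))) {
    phyUse <- new("Phylogeny", tree = phylogeny@tree,
                  labels = rep("", length(phylogeny@labels)),
                  rooted = phylogeny@rooted)
  }
  prep <- prepareLikelihood(aln, phyUse)
  classes <- prep$classTokens
  if (!"background" %in% classes) classes <- c("background", classes)
  nC <- length(classes)
  negLL <- function(p) {
    v <- -logLikPrepared(prep, exp(p[1]), setNames(exp(p[-1]), classes), codonFreqs)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(log(0.01), rep(log(1e-4), nC))
  upper <- c(log(50), rep(log(20), nC))
  tryFit <- function(k0, w0) {
    par0 <- pmin(pmax(c(log(k0), rep(log(w0), nC)), lower), upper)
    if (!is.finite(logLikPrepared(prep, exp(par0[1]),
                                  setNames(exp(par0[-1]), classes), codonFreqs)))
      return(NULL)
    optim(par0, negLL, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(factr = 1e7, maxit = 300))
  }
  opt <- tryFit(startKappa, startOmega)
  if (is.null(opt)) opt <- tryFit(2, 0.5)
  if (is.null(opt)) stop("non-finite likelihood at both requested and fallback starts")
  omega <- setNames(exp(opt$par[-1]), classes)
  new("EngineFit", kappa = exp(opt$par[1]), omega = omega,
      codonFreqs = codonFreqs, lnl = -opt$value, np = 1L + nC,
      converged = opt$convergence == 0L)
}
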