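## Bivariate normal density with common mean/scale on both coordinates.
dbinorm <- function(z1, z2, mu, sigma, rho) {
  s2 <- sigma^2
  q <- ((z1 - mu)^2 - 2 * rho * (z1 - mu) * (z2 - mu) + (z2 - mu)^2) /
    (s2 * (1 - rho^2))
  exp(-q / 2) / (2 * pi * s2 * sqrt(1 - rho^2))
}

## Inverse of the mixture marginal CDF
## G(z) = (1 - p) * pnorm(z) + p * pnorm(z, mu, sigma), by grid interpolation.
mixtureQuantile <- function(u, p, mu, sigma) {
  lo <- min(-6, mu - 6 * sigma)
  hi <- max(6, mu + 6 * sigma)
  zg <- seq(lo, hi, length.out = 4096L)
  Gg <- (1 - p) * stats::pnorm(zg) + p * stats::pnorm(zg, mu, sigma)
  stats::approx(Gg, zg, xout = u, rule = 2, ties = "ordered")$y
}

## Bounded parameter transforms keep the optimiser away from numerically
## degenerate corners (huge mu/sigma make the quantile grid meaningless).
idrBounds <- list(p = c(1e-4, 0.9999), mu = c(0.01, 8),
                  sigma = c(0.2, 5), rho = c(0, 0.9999))
toBounded <- function(t, b) b[1] + (b[2] - b[1]) * stats::plogis(t)
fromBounded <- function(x, b) stats::qlogis((x - b[1]) / (b[2] - b[1]))
unpackIdrPar <- function(t) list(p = toBounded(t[1], idrBounds$p),
                                 mu = toBounded(t[2], idrBounds$mu),
                                 sigma = toBounded(t[3], idrBounds$sigma),
                                 rho = toBounded(t[4], idrBounds$rho))
packIdrPar <- function(p, mu, sigma, rho)
  c(fromBounded(p, idrBounds$p), fromBounded(mu, idrBounds$mu),
    fromBounded(sigma, idrBounds$sigma), fromBounded(rho, idrBounds$rho))

#' Estimate the irreproducible discovery rate for matched replicate peaks
#'
#' Fits the rank-based two-component Gaussian copula mixture to the two
#' replicate score vectors of a matched pair set. Scores are reduced to
#' ranks, mapped to uniform pseudo-values \eqn{u_i = r_i / (n + 1)}, and
#' transformed to pseudo-data \eqn{z_i = G^{-1}(u_i)} under the mixture
#' marginal \eqn{G}; the copula log-likelihood (joint mixture density over
#' the product of its marginals, so only the dependence structure is
#' scored) is maximised directly over the four parameters — reproducible
#' weight \code{p}, mean \code{mu}, scale \code{sigma}, correlation
#' \code{rho}, with the irreproducible component fixed at standard
#' independent normal — by Nelder-Mead from a fixed set of starts
#' (including p = 0.5, mu = 1, sigma = 1, rho = 0.2), under a weak
#' \eqn{\log(1 - p)} penalty that resolves the label ambiguity of
#' dependence-free data toward "irreproducible". When the likelihood-ratio
#' gain over the independence null falls below \eqn{\chi^2_{3,0.99}/2} the
#' fit is declared signal-free: no pair is called reproducible.
#'
#' The local idr of a pair is the posterior probability of the
#' irreproducible component; the global IDR of a pair is the running mean
#' of local idr over all pairs at least as reproducible, i.e. the expected
#' irreproducible fraction of the selected set when thresholding at that
#' pair.
#'
#' @param pairs \code{GRanges} from [overlapReplicates()] (at least 20
#'   pairs; fewer is an error, the fit is unstable).
#' @param score which per-replicate score to rank: \code{"fold_enrichment"}
#'   (mcols \code{fold1}/\code{fold2}, the default) or \code{"neg_log10_q"}
#'   (\code{q1}/\code{q2}).
#' @param maxit maximum optimiser iterations per start (default 2000).
#' @return an [IdrFit-class]; \code{localIdr}/\code{globalIdr} follow the
#'   input pair order, and the \code{loglik} slot traces the penalised
#'   copula log-likelihood over the best run's evaluations.
#' @references Li, Q., Brown, J.B., Huang, H., Bickel, P.J. (2011)
#'   Measuring reproducibility of high-throughput experiments.
#'   Ann. Appl. Stat. 5, 1752-1779.
#' @export
estimateIdr <- function(pairs, score = c("fold_enrichment", "neg_log10_q"),
                        maxit = 2000L) {
  score <- match.arg(score)
  n <- length(pairs)
  if (n < 20L)
    stop("estimateIdr needs at least 20 matched pairs (got ", n,
         "); the mixture fit is unstable below that")
  if (score == "fold_enrichment") {
    s1 <- pairs$fold1; s2 <- pairs$fold2
  } else {
    s1 <- pairs$q1; s2 <- pairs$q2
  }
  if (length(unique(s1)) == 1L || length(unique(s2)) == 1L)
    stop("degenerate scores (all tied) in at least one replicate; ",
         "cannot rank for IDR")
  u1 <- rank(s1, ties.method = "average") / (n + 1)
  u2 <- rank(s2, ties.method = "average") / (n + 1)

  copll <- function(par) {
    z1 <- mixtureQuantile(u1, par$p, par$mu, par$sigma)
    z2 <- mixtureQuantile(u2, par$p, par$mu, par$sigma)
    g1 <- (1 - par$p) * stats::dnorm(z1) + par$p * stats::dnorm(z1, par$mu, par$sigma)
    g2 <- (1 - par$p) * stats::dnorm(z2) + par$p * stats::dnorm(z2, par$mu, par$sigma)
    h <- par$p * dbinorm(z1, z2, par$mu, par$sigma, max(par$rho, 1e-6)) +
      (1 - par$p) * stats::dnorm(z1) * stats::dnorm(z2)
    sum(log(pmax(h, 1e-300)) - log(pmax(g1, 1e-300)) - log(pmax(g2, 1e-300)))
  }
  traceEnv <- new.env()
  traceEnv$cur <- numeric(0)
  negll <- function(t) {
    par <- unpackIdrPar(t)
    val <- -(copll(par) + log(1 - par$p))
    traceEnv$cur <- c(traceEnv$cur, -val)
    val
  }
  starts <- list(packIdrPar(0.5, 1, 1, 0.2),
                 packIdrPar(0.9, 2, 1, 0.9),
                 packIdrPar(0.05, 1, 1, 0.05))
  best <- NULL; bestTrace <- numeric(0)
  for (t0 in starts) {
    traceEnv$cur <- numeric(0)
    opt <- stats::optim(t0, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      bestTrace <- traceEnv$cur
    }
  }
  if (best$convergence == 1L) {
    cond <- structure(class = c("idrConvergenceError", "error", "condition"),
                      list(message = paste0("IDR fit did not converge in ",
                                            maxit, " iterations"),
                           call = sys.call(-1), loglik = bestTrace))
    stop(cond)
  }
  par <- unpackIdrPar(best$par)
  lr <- copll(par)
  if (lr < stats::qchisq(0.99, 3) / 2) {
    ## no significant dependence: call everything irreproducible
    par$p <- idrBounds$p[1]
    par$rho <- 0
  }
  z1 <- mixtureQuantile(u1, par$p, par$mu, par$sigma)
  z2 <- mixtureQuantile(u2, par$p, par$mu, par$sigma)
  f1 <- dbinorm(z1, z2, par$mu, par$sigma, max(par$rho, 1e-6))
  f0 <- stats::dnorm(z1) * stats::dnorm(z2)
  den <- par$p * f1 + (1 - par$p) * f0
  w <- ifelse(den > 0, par$p * f1 / den, 0.5)
  w[!is.finite(w)] <- 0.5
  local <- pmin(pmax(1 - w, 0), 1)
  o <- order(local)
  glob <- numeric(n)
  glob[o] <- cumsum(local[o]) / seq_len(n)
  new("IdrFit", p = par$p, mu = par$mu, sigma = par$sigma,
      rho = min(max(par$rho, -0.9999), 0.9999),
      localIdr = local, globalIdr = pmin(pmax(glob, 0), 1),
      loglik = bestTrace, converged = TRUE)
}
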