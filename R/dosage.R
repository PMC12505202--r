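# Allele-dosage calling from Ref/Alt read counts.
#
# Emission model per marker: alt reads ~ BetaBinomial(depth, xi(d), rho)
# where d in 0..m is the latent dosage, rho the overdispersion, and
#   xi0(d) = (d/m)(1-eps) + (1-d/m) eps        (sequencing error eps)
#   xi(d)  = xi0 / (h (1-xi0) + xi0)           (allele bias h > 0)
# Genotype priors: "norm" = a normal density over dosages (mean mu, sd
# sigma) renormalized on 0..m, suited to panels of unrelated accessions;
# "f1" = the Mendelian gamete-combination distribution implied by the two
# parents' dosages, suited to biparental diploid populations.
# Parameters are estimated per marker by (generalized) EM over the latent
# dosages, so the marginal log-likelihood is non-decreasing by iteration.

#' Expected alternative-read fraction for a dosage
#'
#' Maps a dosage `d` of ploidy `m` to the expected fraction of alternative
#' reads under sequencing error `eps` and allele bias `h`. `h = 1`,
#' `eps = 0` gives `d/m`; `h > 1` depresses the alternative allele.
#'
#' @param d Dosage (0..m), vectorized.
#' @param m Ploidy.
#' @param h Allele bias, > 0.
#' @param eps Sequencing error rate in [0, 0.5).
#' @return Expected alt-read fraction(s) in [0, 1], strictly increasing in
#'   `d` for any valid `h`, `eps`.
#' @export
xi_fun <- function(d, m, h = 1, eps = 0) {
  stopifnot(h > 0, eps >= 0, eps < 0.5)
  xi0 <- (d / m) * (1 - eps) + (1 - d / m) * eps
  xi0 / (h * (1 - xi0) + xi0)
}

#' Beta-binomial density
#'
#' Mean/overdispersion parameterization: `mu` is the success fraction and
#' `rho` in [0, 1) the intra-class correlation; `rho -> 0` recovers the
#' binomial.
#'
#' @param x Number of successes.
#' @param size Number of trials.
#' @param mu Mean fraction in (0, 1).
#' @param rho Overdispersion in [0, 1).
#' @param log Return log density?
#' @return (Log-)density, vectorized over `x`/`size`/`mu`.
#' @export
dbetabinom <- function(x, size, mu, rho = 0, log = FALSE) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  if (all(rho < 1e-9)) {
    ll <- stats::dbinom(x, size, mu, log = TRUE)
  } else {
    s <- (1 - rho) / rho
    a <- mu * s
    b <- (1 - mu) * s
    ll <- lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
  }
  if (log) ll else exp(ll)
}

# discretized-normal genotype prior on 0..m
.norm_prior <- function(m, mu, sigma) {
  p <- stats::dnorm(0:m, mu, max(sigma, 1e-3))
  p <- p + 1e-12
  p / sum(p)
}

# Mendelian offspring dosage distribution for diploid parents d1, d2
.f1_prior <- function(d1, d2, m = 2L) {
  gam <- function(d) switch(as.character(d),
    "0" = c(1, 0), "1" = c(0.5, 0.5), "2" = c(0, 1))
  g1 <- gam(d1); g2 <- gam(d2)
  p <- c(g1[1] * g2[1], g1[1] * g2[2] + g1[2] * g2[1], g1[2] * g2[2])
  p <- p + 1e-12
  p / sum(p)
}

# emission log-lik matrix: samples x (m+1)
.emit_ll <- function(alt, depth, m, h, rho, eps) {
  xi <- xi_fun(0:m, m, h, eps)
  vapply(0:m, function(d)
    dbetabinom(alt, depth, xi[d + 1L], rho, log = TRUE),
    numeric(length(alt)))
}

.marginal_ll <- function(alt, depth, m, h, rho, eps, log_prior) {
  ll <- .emit_ll(alt, depth, m, h, rho, eps)
  ll <- sweep(ll, 2L, log_prior, `+`)
  mx <- apply(ll, 1L, max)
  sum(mx + log(rowSums(exp(ll - mx))))
}

# one-marker generalized EM. prior_type "norm" (mu/sigma updated) or
# "fixed" (prior given, only h/rho/eps updated).
.fit_marker_em <- function(alt, depth, m, prior_type = c("norm", "fixed"),
                           prior = NULL, init = NULL,
                           max_iter = 200L, tol = 1e-6) {
  prior_type <- match.arg(prior_type)
  n <- length(alt)
  h <- if (is.null(init$h)) 1 else init$h
  eps <- if (is.null(init$eps)) 0.005 else init$eps
  rho <- if (is.null(init$rho)) 0.01 else init$rho
  mu <- if (is.null(init$mu)) m * sum(alt) / max(sum(depth), 1) else init$mu
  sigma <- if (is.null(init$sigma)) m / 4 else init$sigma
  pr <- if (prior_type == "norm") .norm_prior(m, mu, sigma) else prior

  trans <- function(h, rho, eps) c(log(h), stats::qlogis(rho), stats::qlogis(eps / 0.5))
  untrans <- function(p) list(h = exp(p[1]),
                              rho = stats::plogis(p[2]),
                              eps = 0.5 * stats::plogis(p[3]))
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    lem <- .emit_ll(alt, depth, m, h, rho, eps)
    lw <- sweep(lem, 2L, log(pr), `+`)
    mx <- apply(lw, 1L, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    w <- exp(lw - mx - log(rowSums(exp(lw - mx))))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M-step, prior parameters
    if (prior_type == "norm") {
      Wd <- colSums(w)
      obj_p <- function(p) -sum(Wd * log(.norm_prior(m, p[1], exp(p[2]))))
      op <- stats::optim(c(mu, log(sigma)), obj_p,
                         method = "Nelder-Mead", control = list(maxit = 40L))
      mu <- op$par[1]; sigma <- exp(op$par[2])
      pr <- .norm_prior(m, mu, sigma)
    }
    # M-step, emission parameters
    obj_e <- function(p) {
      q <- untrans(p)
      if (q$h < 1e-3 || q$h > 1e3) return(1e12)
      -sum(w * .emit_ll(alt, depth, m, q$h, q$rho, q$eps))
    }
    oe <- stats::optim(trans(h, rho, eps), obj_e,
                       method = "Nelder-Mead", control = list(maxit = 40L))
    q <- untrans(oe$par)
    h <- q$h; rho <- q$rho; eps <- q$eps
  }
  # final posteriors
  lem <- .emit_ll(alt, depth, m, h, rho, eps)
  lw <- sweep(lem, 2L, log(pr), `+`)
  mx <- apply(lw, 1L, max)
  w <- exp(lw - mx - log(rowSums(exp(lw - mx))))
  list(h = h, rho = rho, eps = eps, mu = mu, sigma = sigma,
       prior = pr, posterior = w, loglik = ll_old,
       ll_trace = ll_trace, converged = converged, n_used = n)
}

.fit_marker <- function(alt, depth, m, prior_type, prior = NULL,
                        max_iter = 200L, tol = 1e-6, n_restart = 3L,
                        seed = NULL) {
  fit <- .fit_marker_em(alt, depth, m, prior_type, prior,
                        max_iter = max_iter, tol = tol)
  if (!fit$converged && n_restart > 0L) {
    for (k in seq_len(n_restart)) {
      init <- list(h = exp(stats::rnorm(1, 0, 0.5)),
                   eps = stats::runif(1, 0.001, 0.05),
                   rho = stats::runif(1, 0.001, 0.05),
                   mu = stats::runif(1, 0, m), sigma = m / 4)
      f2 <- .fit_marker_em(alt, depth, m, prior_type, prior, init,
                           max_iter = max_iter, tol = tol)
      if (f2$loglik > fit$loglik) fit <- f2
    }
  }
  fit
}

#' Construct a genotype matrix container
#'
#' @param dosage Integer matrix, loci x samples, entries 0..ploidy or NA.
#' @param posterior Matrix of the posterior probability of each call.
#' @param ploidy Per-sample ploidy (recycled if scalar).
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, posterior = NULL, ploidy) {
  ploidy <- rep(ploidy, length.out = ncol(dosage))
  bad <- sweep(dosage, 2L, ploidy, `>`)
  if (any(bad, na.rm = TRUE)) stop("dosage exceeds sample ploidy")
  structure(list(dosage = dosage, posterior = posterior, ploidy = ploidy),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d samples (ploidy %s)\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(unique(x$ploidy), collapse = "/")))
  invisible(x)
}

#' Call dosages with the population ("norm") prior
#'
#' Fits, per marker, the beta-binomial dosage mixture with a discretized
#' normal genotype prior by EM, and calls each observed cell at the
#' posterior mode. Cells with fewer than `min_reads` total reads are
#' missing and never enter the fit.
#'
#' @param counts A [count_matrix()].
#' @param m Ploidy at which to call (scalar; run groups separately for
#'   mixed-ploidy panels).
#' @param min_reads Per-cell read threshold (default 10).
#' @param min_samples Minimum observed samples per marker to attempt a fit.
#' @param max_iter,tol EM control.
#' @return List with `fits` (data frame: marker, m, h, rho, eps, mu, sigma,
#'   prop_mis, loglik, converged, n_used), `geno` (a [genotype_matrix()]),
#'   and `ll_traces` (per-marker log-likelihood traces).
#' @export
fit_norm_model <- function(counts, m, min_reads = 10L, min_samples = 5L,
                           max_iter = 200L, tol = 1e-6) {
  .fit_model(counts, m, prior_fun = NULL, min_reads = min_reads,
             min_samples = min_samples, max_iter = max_iter, tol = tol)
}

#' Call dosages with the biparental ("f1") prior
#'
#' Parent dosages are estimated first from the parents' own reads
#' (maximum likelihood under a neutral emission model) and then fixed; the
#' offspring prior at each marker is the Mendelian gamete-combination
#' distribution those dosages imply. Markers where either parent is
#' missing fall back to the "norm" prior with a warning.
#'
#' @param counts A [count_matrix()] containing parents and offspring.
#' @param parents Character vector of the two parent sample ids.
#' @param m Ploidy (2; diploid biparental populations).
#' @inheritParams fit_norm_model
#' @return As [fit_norm_model()]; `fits` gains `p1_dosage`, `p2_dosage`.
#' @export
fit_f1_model <- function(counts, parents, m = 2L, min_reads = 10L,
                         min_samples = 5L, max_iter = 200L, tol = 1e-6) {
  stopifnot(length(parents) == 2L)
  if (!all(parents %in% counts$samples$sample_id))
    stop("parent sample(s) not found: ",
         paste(setdiff(parents, counts$samples$sample_id), collapse = ", "))
  pd <- parent_dosages(counts, parents, m = m, min_reads = min_reads)
  prior_fun <- function(i) {
    d1 <- pd[i, 1L]; d2 <- pd[i, 2L]
    if (is.na(d1) || is.na(d2)) NULL else .f1_prior(d1, d2, m)
  }
  out <- .fit_model(counts, m, prior_fun = prior_fun, min_reads = min_reads,
                    min_samples = min_samples, max_iter = max_iter, tol = tol,
                    offspring = setdiff(counts$samples$sample_id, parents))
  out$fits$p1_dosage <- pd[, 1L]
  out$fits$p2_dosage <- pd[, 2L]
  n_fb <- sum(is.na(pd[, 1L]) | is.na(pd[, 2L]))
  if (n_fb > 0L)
    warning(n_fb, " marker(s) with a missing parent fell back to the norm prior")
  out
}

#' Estimate parent dosages from their own reads
#'
#' Maximum-likelihood dosage per parent and marker under a neutral
#' emission (h = 1, eps = 0.005, rho = 0.01) with a uniform prior.
#'
#' @inheritParams fit_f1_model
#' @return Matrix loci x 2 of parent dosages (NA where below `min_reads`).
#' @export
parent_dosages <- function(counts, parents, m = 2L, min_reads = 10L) {
  j <- match(parents, counts$samples$sample_id)
  out <- matrix(NA_integer_, nrow(counts$ref), 2L,
                dimnames = list(counts$markers$locus_id, parents))
  for (k in 1:2) {
    a <- counts$alt[, j[k]]
    n <- counts$ref[, j[k]] + a
    ok <- n >= min_reads
    if (!any(ok)) next
    ll <- vapply(0:m, function(d)
      dbetabinom(a[ok], n[ok], xi_fun(d, m, 1, 0.005), 0.01, log = TRUE),
      numeric(sum(ok)))
    out[ok, k] <- max.col(ll) - 1L
  }
  out
}

# shared driver for norm/f1 fitting
.fit_model <- function(counts, m, prior_fun, min_reads, min_samples,
                       max_iter, tol, offspring = NULL) {
  total <- counts$ref + counts$alt
  obs <- total >= min_reads
  p <- nrow(total); ns <- ncol(total)
  fit_cols <- if (is.null(offspring)) seq_len(ns)
              else match(offspring, counts$samples$sample_id)
  dosage <- matrix(NA_integer_, p, ns,
                   dimnames = dimnames(counts$ref))
  post <- matrix(NA_real_, p, ns, dimnames = dimnames(counts$ref))
  fits <- data.frame(marker = counts$markers$locus_id, m = m,
                     h = NA_real_, rho = NA_real_, eps = NA_real_,
                     mu = NA_real_, sigma = NA_real_,
                     prop_mis = NA_real_, loglik = NA_real_,
                     converged = NA, n_used = 0L,
                     stringsAsFactors = FALSE)
  traces <- vector("list", p)
  n_nonconv <- 0L
  for (i in seq_len(p)) {
    jj <- fit_cols[obs[i, fit_cols]]
    if (length(jj) < min_samples) next
    pr <- if (is.null(prior_fun)) NULL else prior_fun(i)
    ptype <- if (is.null(pr)) "norm" else "fixed"
    fit <- .fit_marker(counts$alt[i, jj], total[i, jj], m,
                       prior_type = ptype, prior = pr,
                       max_iter = max_iter, tol = tol)
    calls <- max.col(fit$posterior) - 1L
    mp <- fit$posterior[cbind(seq_along(jj), calls + 1L)]
    dosage[i, jj] <- calls
    post[i, jj] <- mp
    fits$h[i] <- fit$h; fits$rho[i] <- fit$rho; fits$eps[i] <- fit$eps
    fits$mu[i] <- fit$mu; fits$sigma[i] <- fit$sigma
    fits$prop_mis[i] <- mean(1 - mp)
    fits$loglik[i] <- fit$loglik
    fits$converged[i] <- fit$converged
    fits$n_used[i] <- length(jj)
    traces[[i]] <- fit$ll_trace
    if (!fit$converged) n_nonconv <- n_nonconv + 1L
  }
  if (n_nonconv > 0L)
    warning(n_nonconv, " marker(s) did not converge; retained and flagged")
  list(fits = fits,
       geno = genotype_matrix(dosage, post, ploidy = m),
       ll_traces = traces)
}

#' Post-dosage marker filters
#'
#' Retains a marker when its estimated allele bias lies strictly inside
#' `bias_bounds`, its misclassification proportion (mean of one minus the
#' maximum posterior) is below `max_prop_mis`, and its overdispersion is
#' below `max_od`.
#'
#' @param fits The `fits` data frame from a dosage fit.
#' @param bias_bounds Open interval for `h` (default (0.05, 2)).
#' @param max_prop_mis Upper bound on misclassification (default 0.1).
#' @param max_od Upper bound on overdispersion (default 0.05).
#' @return List with `keep` (logical per marker; NA-fit markers FALSE) and
#'   `log`, a data frame of per-rule verdicts.
#' @export
filter_postdosage <- function(fits, bias_bounds = c(0.05, 2),
                              max_prop_mis = 0.1, max_od = 0.05) {
  ok_bias <- fits$h > bias_bounds[1] & fits$h < bias_bounds[2]
  ok_mis <- fits$prop_mis < max_prop_mis
  ok_od <- fits$rho < max_od
  keep <- !is.na(ok_bias) & !is.na(ok_mis) & !is.na(ok_od) &
    ok_bias & ok_mis & ok_od
  list(keep = keep,
       log = data.frame(marker = fits$marker, ok_bias = ok_bias,
                        ok_prop_mis = ok_mis, ok_od = ok_od, keep = keep,
                        stringsAsFactors = FALSE))
}

#' Informative markers
#'
#' A marker is informative when at least two distinct non-missing dosages
#' occur among the evaluated samples.
#'
#' @param geno A [genotype_matrix()] or a dosage matrix.
#' @return Logical vector per marker.
#' @export
informative_markers <- function(geno) {
  d <- if (inherits(geno, "genotype_matrix")) geno$dosage else geno
  apply(d, 1L, function(x) length(unique(x[!is.na(x)])) >= 2L)
}
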