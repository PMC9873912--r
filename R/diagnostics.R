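#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor in the rank-normalized split form: each
#' chain is split in half, all draws are rank-normalized through the normal
#' quantile function, and the classic between/within variance ratio is
#' computed on the transformed draws and on their folded (absolute
#' deviation from the median) counterparts; the larger of the two is
#' reported. Values near 1 indicate convergence.
#'
#' @param chains an iterations x chains matrix, or a list of equal-length
#'   numeric vectors (one per chain). At least 2 chains of >= 10 draws.
#' @return The split R-hat (scalar).
#' @export
rhat <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop_input("R-hat needs at least 2 chains")
  if (nrow(chains) < 10) stop_input("R-hat needs at least 10 draws per chain")
  half <- floor(nrow(chains) / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[half + seq_len(half), , drop = FALSE])
  if (all(abs(split - split[1]) < 1e-300)) return(1)
  base_rhat <- function(z) {
    n <- nrow(z)
    W <- mean(apply(z, 2, var))
    B <- n * var(colMeans(z))
    if (W < 1e-300) return(Inf)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  znorm <- function(m) {
    r <- rank(m, ties.method = "average")
    matrix(qnorm((r - 3 / 8) / (length(m) + 1 / 4)), nrow(m), ncol(m))
  }
  bulk <- base_rhat(znorm(split))
  folded <- base_rhat(znorm(abs(split - median(split))))
  max(bulk, folded)
}

#' Effective sample sizes of monitored parameters
#'
#' @param fit a `carn_fit`.
#' @param terms terms to report (default all slope terms plus the intercept
#'   and residual sd).
#' @return Named numeric vector of effective sample sizes (all chains
#'   pooled), computed with [coda::effectiveSize()].
#' @export
effective_sizes <- function(fit, terms = NULL) {
  if (is.null(terms)) terms <- fit$design$term_names
  ml <- function(m) coda::as.mcmc.list(
    lapply(seq_len(ncol(m)), function(j) coda::mcmc(m[, j])))
  out <- c(alpha = sum(coda::effectiveSize(ml(chain_matrix(fit, "alpha")))),
           sigma = sum(coda::effectiveSize(ml(chain_matrix(fit, "sigma")))))
  for (term in terms) {
    m <- chain_matrix(fit, "b", term) * chain_matrix(fit, "gamma", term)
    out[paste0("b:", term)] <- sum(coda::effectiveSize(ml(m)))
  }
  out
}

#' Moran's I with inverse great-circle-distance weights
#'
#' Tests model residuals for spatial autocorrelation. Weights are inverse
#' great-circle distances (zero diagonal, row-standardized); the expected
#' value under no autocorrelation is `-1/(n-1)`, and the p-value comes from
#' permuting residuals over locations (two-sided, seeded).
#'
#' @param residuals per-record residual values.
#' @param latitude,longitude coordinates in decimal degrees (WGS84).
#' @param n_permutations permutation count (default 999).
#' @param seed integer seed for the permutation null.
#' @param jitter if `TRUE`, duplicated coordinates are jittered by up to
#'   ~10 m instead of raising an error.
#' @return List with `I`, `expected`, `p`, `n`, `n_permutations`.
#' @export
morans_i <- function(residuals, latitude, longitude, n_permutations = 999,
                     seed = 1, jitter = FALSE) {
  n <- length(residuals)
  if (n < 5) stop_input("Moran's I needs at least 5 records")
  if (length(latitude) != n || length(longitude) != n)
    stop_input("coordinate vectors must match the residuals")
  if (sd(residuals) == 0)
    stop_input("Moran's I is undefined for constant residuals")
  pts <- cbind(longitude, latitude)
  if (anyDuplicated(pts)) {
    if (!jitter)
      stop_input("duplicate coordinates; set jitter = TRUE to proceed")
    pts <- with_seed(seed, pts + matrix(runif(2 * n, -1e-4, 1e-4), n, 2))
  }
  D <- geosphere::distm(pts)
  W <- 1 / D
  diag(W) <- 0
  W <- W / rowSums(W)
  S0 <- sum(W)
  stat <- function(z) {
    zc <- z - mean(z)
    (n / S0) * drop(zc %*% W %*% zc) / sum(zc^2)
  }
  I <- stat(residuals)
  E <- -1 / (n - 1)
  perm <- with_seed(substream_seed(seed, "permutation"),
    vapply(seq_len(n_permutations),
           function(k) stat(sample(residuals)), 0))
  p <- (1 + sum(abs(perm - E) >= abs(I - E))) / (n_permutations + 1)
  list(I = I, expected = E, p = p, n = n, n_permutations = n_permutations)
}

#' Taxonomy tree from the genus/species nesting
#'
#' Builds the default phylogeny used when no Newick tree is supplied: each
#' genus is a clade of its species, with unit branch lengths. Coarse, but it
#' lets the phylogenetic-signal diagnostic run on data whose only structure
#' is taxonomic.
#'
#' @param species,genus character vectors (parallel, one entry per record or
#'   per species).
#' @return An [ape::read.tree()] phylogeny whose tips are the species.
#' @export
taxonomy_tree <- function(species, genus) {
  map <- unique(data.frame(species = as.character(species),
                           genus = as.character(genus)))
  if (anyDuplicated(map$species))
    stop_input("species assigned to more than one genus")
  clades <- vapply(split(map$species, map$genus), function(sp) {
    if (length(sp) == 1) paste0(sp, ":1")
    else paste0("(", paste0(sp, ":1", collapse = ","), "):1")
  }, "")
  if (length(clades) == 1)
    txt <- paste0("(", paste0(map$species, ":1", collapse = ","), ");")
  else
    txt <- paste0("(", paste(clades, collapse = ","), ");")
  ape::collapse.singles(ape::read.tree(text = txt))
}

#' Pagel's lambda phylogenetic signal in residuals
#'
#' Maximum-likelihood lambda for the Brownian-motion covariance whose
#' off-diagonal entries are scaled by lambda, with a likelihood-ratio test
#' against lambda = 0. Residuals are averaged per species before testing. A
#' star phylogeny has no internal structure to scale, so lambda is 0 by
#' convention. The estimate is invariant to rescaling all branch lengths by
#' a constant.
#'
#' @param residuals numeric vector of per-record (or per-species) values.
#' @param species species label per value (ignored if `residuals` is
#'   already named by species).
#' @param tree optional phylogeny with branch lengths; defaults to the
#'   [taxonomy_tree()] built from `genus`.
#' @param genus genus labels (needed only for the default tree).
#' @return List with `lambda` (in `[0, 1]`), `logL`, `logL0` and `p` (LR
#'   test against lambda = 0).
#' @export
pagels_lambda <- function(residuals, species = names(residuals),
                          tree = NULL, genus = NULL) {
  if (is.null(species)) stop_input("species labels are required")
  x <- tapply(residuals, as.character(species), mean)
  if (is.null(tree)) {
    if (is.null(genus)) stop_input("supply a tree or genus labels")
    map <- unique(data.frame(species = as.character(species),
                             genus = as.character(genus)))
    tree <- taxonomy_tree(map$species, map$genus)
  }
  absent <- setdiff(names(x), tree$tip.label)
  if (length(absent))
    stop_input("species missing from the tree: ",
               paste(absent, collapse = ", "))
  if (length(setdiff(tree$tip.label, names(x))))
    tree <- ape::keep.tip(tree, names(x))
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  if (tree$Nnode <= 1)
    return(list(lambda = 0, logL = NA_real_, logL0 = NA_real_, p = 1,
                note = "star phylogeny: lambda unidentifiable, 0 by convention"))
  res <- phytools::phylosig(tree, x[tree$tip.label], method = "lambda",
                            test = TRUE)
  list(lambda = min(max(res$lambda, 0), 1), logL = res$logL,
       logL0 = res$logL0, p = res$P)
}

#' Posterior predictive check
#'
#' For each retained draw, replicate responses are simulated from the
#' fitted model (`y_rep ~ Normal(mu, sigma/sqrt(w))`, with the trend-fit se
#' added where present); censored records are simulated on the latent scale
#' and then categorized through the disjoint partition at +-5. Observed
#' quantiles of the quantitative records (5/25/50/75/95 percent) and the
#' observed qualitative category proportions are compared with their
#' replicate distributions; posterior predictive p-values near 0 or 1 flag
#' misfit.
#'
#' @param fit a `carn_fit`.
#' @param seed integer seed for the replicate noise.
#' @return A data.frame: statistic, observed value, replicate mean, 2.5 and
#'   97.5 percent replicate quantiles, and the posterior predictive p-value
#'   `P(rep >= obs)`.
#' @export
posterior_predictive_check <- function(fit, seed = 1) {
  design <- fit$design
  if (!length(design$y)) stop_input("no records to check")
  MU <- fitted_draws(fit)
  sigma <- combined(fit, "sigma")
  S <- nrow(MU); n <- ncol(MU)
  sd_rec <- sqrt(outer(sigma^2, 1 / design$w) +
                   matrix(design$se2, S, n, byrow = TRUE))
  YR <- with_seed(substream_seed(seed, "ppc"),
                  MU + matrix(rnorm(S * n), S, n) * sd_rec)
  quant <- design$is_cens == 0
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- list()
  if (any(quant)) {
    obs_q <- quantile(design$y[quant], probs)
    rep_q <- t(apply(YR[, quant, drop = FALSE], 1, quantile, probs))
    for (k in seq_along(probs)) {
      rows[[length(rows) + 1]] <- data.frame(
        statistic = sprintf("q%02d", probs[k] * 100),
        observed = obs_q[k], rep_mean = mean(rep_q[, k]),
        rep_lo = quantile(rep_q[, k], 0.025),
        rep_hi = quantile(rep_q[, k], 0.975),
        ppp = mean(rep_q[, k] >= obs_q[k]))
    }
  }
  if (any(!quant)) {
    obs_cat <- categorize_trend(rowMeans(design$lim[!quant, , drop = FALSE]))
    for (cat in c("Decrease", "Stable", "Increase")) {
      obs_p <- mean(obs_cat == cat)
      rep_p <- rowMeans(matrix(
        categorize_trend(YR[, !quant, drop = FALSE]) == cat, S))
      rows[[length(rows) + 1]] <- data.frame(
        statistic = paste0("prop_", cat), observed = obs_p,
        rep_mean = mean(rep_p), rep_lo = quantile(rep_p, 0.025),
        rep_hi = quantile(rep_p, 0.975), ppp = mean(rep_p >= obs_p))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Conditional and marginal R-squared
#'
#' Variance explained by fixed effects alone (marginal) and by fixed plus
#' random effects (conditional), computed per draw as variance ratios:
#' `marginal = var(fixed) / (var(fixed) + sum(var(random)) + var(residual))`
#' with the random-intercept variances taken from their posterior draws and
#' the residual variance averaged over the record-level weights. Summarised
#' by the posterior median.
#'
#' @param fit a `carn_fit`.
#' @return List with `conditional`, `marginal` (medians) and a `draws`
#'   data.frame.
#' @export
conditional_r2 <- function(fit) {
  MUF <- fitted_draws(fit, include_random = FALSE)
  var_f <- apply(MUF, 1, var)
  SD <- do.call(rbind, lapply(fit$chains, `[[`, "sd_re"))
  var_r <- rowSums(SD^2)
  sigma <- combined(fit, "sigma")
  var_e <- sigma^2 * mean(1 / fit$design$w) + mean(fit$design$se2)
  marg <- var_f / (var_f + var_r + var_e)
  cond <- (var_f + var_r) / (var_f + var_r + var_e)
  list(conditional = median(cond), marginal = median(marg),
       draws = data.frame(conditional = cond, marginal = marg))
}

#' Full diagnostics report for a fitted model
#'
#' Convergence (rank-normalized split R-hat, effective sizes), spatial
#' residual autocorrelation (Moran's I), phylogenetic residual signal
#' (Pagel's lambda, on a supplied Newick phylogeny or the taxonomy tree),
#' posterior predictive checks, and conditional/marginal R-squared.
#'
#' @param fit a `carn_fit`.
#' @param tree optional phylogeny ([ape::phylo]) covering the species.
#' @param n_permutations Moran permutation count.
#' @param seed integer seed (permutations and replicate simulation).
#' @return An object of class `carn_diagnostics`.
#' @export
diagnostics_report <- function(fit, tree = NULL, n_permutations = 199,
                               seed = 1) {
  design <- fit$design
  res <- residuals(fit)
  quant <- design$is_cens == 0
  mor <- morans_i(res, design$latitude[quant], design$longitude[quant],
                  n_permutations = n_permutations, seed = seed,
                  jitter = TRUE)
  lam <- pagels_lambda(res, species = design$species[quant], tree = tree,
                       genus = design$genus[quant])
  r2 <- conditional_r2(fit)
  structure(list(rhat = fit$rhat,
                 ess = effective_sizes(fit),
                 morans = mor, lambda = lam,
                 ppc = posterior_predictive_check(fit, seed = seed),
                 conditional_r2 = r2$conditional,
                 marginal_r2 = r2$marginal),
            class = "carn_diagnostics")
}

#' @export
print.carn_diagnostics <- function(x, ...) {
  cat("Model diagnostics\n")
  cat(sprintf("  max R-hat          : %.3f\n", max(x$rhat, na.rm = TRUE)))
  cat(sprintf("  min effective size : %.0f\n", min(x$ess, na.rm = TRUE)))
  cat(sprintf("  Moran's I          : %.4f (E = %.4f, p = %.3f)\n",
              x$morans$I, x$morans$expected, x$morans$p))
  cat(sprintf("  Pagel's lambda     : %.3f (p = %.3f)\n",
              x$lambda$lambda, x$lambda$p))
  cat(sprintf("  R2 conditional     : %.3f   marginal: %.3f\n",
              x$conditional_r2, x$marginal_r2))
  invisible(x)
}
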