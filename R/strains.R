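#' Mean fold coverage per contig from alignment intervals
#'
#' @param alignments data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open aligned reference interval of one alignment record).
#' @param contig_lengths Named numeric vector of contig lengths (> 0).
#' @return Named numeric vector of mean depth (total aligned bases divided by
#'   contig length) for every contig in `contig_lengths`; contigs without
#'   alignments get 0 with a warning.
#' @export
contig_coverage <- function(alignments, contig_lengths) {
  if (any(contig_lengths <= 0)) stop("contig lengths must be > 0")
  bases <- tapply(alignments$end - alignments$start, alignments$contig, sum)
  cov <- setNames(rep(0, length(contig_lengths)), names(contig_lengths))
  common <- intersect(names(bases), names(cov))
  cov[common] <- bases[common] / contig_lengths[common]
  uncovered <- names(cov)[cov == 0]
  if (length(uncovered)) {
    warning("no alignments on contig(s): ", paste(uncovered, collapse = ", "))
  }
  cov
}

# Negative log-likelihood of the constrained three-class lognormal mixture.
# theta = (log mu_A, g > 0 with mu_B = mu_A * exp(g), log sigma, l_B, l_S)
# where (l_B, l_S) are weight logits relative to class A and the shared-class
# mean is fixed at mu_A + mu_B. Observations may carry weights (e.g. contig
# lengths, since the coverage of a long contig is a tighter average).
mixture_nll <- function(theta, logx, w_obs) {
  mu_a <- exp(theta[1])
  mu_b <- mu_a * exp(theta[2])
  sigma <- exp(theta[3])
  w <- exp(c(0, theta[4], theta[5]))
  w <- w / sum(w)
  mus <- log(c(mu_a, mu_b, mu_a + mu_b))
  dens <- vapply(1:3, function(c) w[c] * dnorm(logx, mus[c], sigma),
                 numeric(length(logx)))
  -sum(w_obs * log(pmax(rowSums(matrix(dens, ncol = 3)), 1e-300)))
}

fit_two_strain_mixture <- function(cov, w_obs) {
  logx <- log(cov)
  # coarse grid over candidate (mu_A, mu_B) pairs; guards against local
  # optima where one class swallows another. Small inputs use every observed
  # coverage as a candidate so that a class represented by only a couple of
  # contigs is still proposed.
  qs <- if (length(cov) <= 80) {
    sort(unique(round(cov, 3)))
  } else {
    unique(quantile(cov, probs = seq(0.02, 0.98, length.out = 25),
                    names = FALSE))
  }
  pairs <- expand.grid(a = qs, b = qs)
  pairs <- pairs[pairs$b > pairs$a * 1.05, , drop = FALSE]
  grid_nll <- vapply(seq_len(nrow(pairs)), function(i) {
    mixture_nll(c(log(pairs$a[i]), log(pairs$b[i] / pairs$a[i]), log(0.15),
                  0, 0), logx, w_obs)
  }, numeric(1))
  top <- pairs[order(grid_nll)[seq_len(min(3L, nrow(pairs)))], , drop = FALSE]
  q <- quantile(cov, c(0.25, 0.5, 0.75))
  inits <- c(lapply(seq_len(nrow(top)), function(i)
    c(log(top$a[i]), log(top$b[i] / top$a[i]), log(0.15), 0, 0)),
    list(c(log(q[[1]]), log(max(q[[2]] / q[[1]], 1.2)), log(0.2), 0, 0),
         c(log(q[[1]]), log(max(q[[3]] / q[[1]], 1.2)), log(0.2), 0, 0),
         c(log(min(cov)), log(2), log(0.15), 0, 0)))
  fits <- list()
  for (init in inits) {
    fit <- tryCatch(
      optim(init, mixture_nll, logx = logx, w_obs = w_obs,
            method = "L-BFGS-B",
            lower = c(log(min(cov) / 4), 1e-6, log(0.02), -8, -8),
            upper = c(log(max(cov) * 2), log(50), log(2), 8, 8)),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1L]] <- fit
  }
  if (!length(fits)) stop("mixture fit failed")
  # near-ties are broken toward the fit with the largest shared-class weight:
  # when a class's own contigs blend into the shared cloud the likelihood is
  # degenerate, and in a co-assembled two-strain species most of the genome
  # is expected to be shared
  nlls <- vapply(fits, `[[`, numeric(1), "value")
  near <- which(nlls <= min(nlls) + 2)
  w_sh <- vapply(fits[near], function(f) {
    w <- exp(c(0, f$par[4], f$par[5])); (w / sum(w))[3]
  }, numeric(1))
  best <- fits[[near[which.max(w_sh)]]]
  theta <- best$par
  mu_a <- exp(theta[1]); mu_b <- mu_a * exp(theta[2])
  w <- exp(c(0, theta[4], theta[5])); w <- w / sum(w)
  list(mu_A = mu_a, mu_B = mu_b, sigma = exp(theta[3]),
       weights = setNames(w, c("A", "B", "shared")),
       nll = best$value)
}

#' Assign contigs of a two-strain species by coverage
#'
#' Fits a three-class mixture of lognormals to contig mean coverages with a
#' common log-scale dispersion and the shared-class mean constrained to
#' `mu_A + mu_B` (contigs present in both strains accumulate the summed
#' coverage of the two strains). When contig lengths are supplied the
#' likelihood is length-weighted, since the mean coverage of a long contig
#' is a much tighter estimate than that of a short one. Contigs are then
#' labeled by the class whose mean is most consistent with their coverage
#' under equal class priors -- the number of contigs in a class reflects
#' assembly fragmentation, not evidence about a new contig -- or
#' `"ambiguous"` when the top two class weights are closer than
#' `ambiguity_margin`. A single-strain model (one lognormal) is compared by
#' BIC; if it wins, all contigs are labeled `"A"` and `single_strain` is set.
#'
#' @param coverages Named numeric vector of contig mean coverages (>= 3
#'   positive values).
#' @param ambiguity_margin Top-two class weight difference under which a
#'   contig is labeled ambiguous.
#' @param lengths Optional numeric vector of contig lengths (same order or
#'   names as `coverages`) used as likelihood weights.
#' @return A list with `assignment` (data.frame: `contig`, `label` in
#'   A/B/shared/ambiguous, `w_A`, `w_B`, `w_shared`), and `model` (list:
#'   `mu_A`, `mu_B`, `sigma`, `weights`, `single_strain`, `bic_two`,
#'   `bic_one`).
#' @export
assign_strain_contigs <- function(coverages, ambiguity_margin = 0.2,
                                  lengths = NULL) {
  keep <- coverages > 0
  cov <- coverages[keep]
  if (length(cov) < 3L) stop("need >= 3 contigs with positive coverage")
  if (is.null(names(cov))) names(cov) <- paste0("contig_", seq_along(cov))
  w_obs <- if (is.null(lengths)) {
    rep(1, length(cov))
  } else {
    w <- as.numeric(lengths[keep])
    w / mean(w) # normalized so the effective n stays the contig count
  }
  logx <- log(cov)
  n <- length(cov)

  mu1 <- sum(w_obs * logx) / sum(w_obs)
  sd1 <- max(sqrt(sum(w_obs * (logx - mu1)^2) / sum(w_obs)), 0.02)
  nll_one <- -sum(w_obs * dnorm(logx, mu1, sd1, log = TRUE))
  bic_one <- 2 * nll_one + 2 * log(n)

  two <- fit_two_strain_mixture(cov, w_obs)
  bic_two <- 2 * two$nll + 5 * log(n)

  if (bic_one <= bic_two) {
    assignment <- data.frame(contig = names(cov), label = "A",
                             w_A = 1, w_B = 0, w_shared = 0)
    model <- list(mu_A = exp(mu1), mu_B = NA_real_, sigma = sd1,
                  weights = c(A = 1, B = 0, shared = 0),
                  single_strain = TRUE, bic_two = bic_two, bic_one = bic_one)
    return(list(assignment = assignment, model = model))
  }

  # classification under equal class priors
  mus <- log(c(two$mu_A, two$mu_B, two$mu_A + two$mu_B))
  post <- vapply(1:3, function(c) dnorm(logx, mus[c], two$sigma), numeric(n))
  post <- matrix(post, ncol = 3)
  post <- post / pmax(rowSums(post), 1e-300)
  lbl <- c("A", "B", "shared")[max.col(post)]
  top2 <- t(apply(post, 1, function(p) sort(p, decreasing = TRUE)[1:2]))
  lbl[top2[, 1] - top2[, 2] < ambiguity_margin] <- "ambiguous"
  assignment <- data.frame(contig = names(cov), label = lbl,
                           w_A = post[, 1], w_B = post[, 2], w_shared = post[, 3])
  rownames(assignment) <- NULL
  model <- list(mu_A = two$mu_A, mu_B = two$mu_B, sigma = two$sigma,
                weights = two$weights, single_strain = FALSE,
                bic_two = bic_two, bic_one = bic_one)
  list(assignment = assignment, model = model)
}

#' Relative strain abundances from a fitted coverage model
#'
#' @param model The `model` element returned by [assign_strain_contigs()].
#' @return Named numeric vector `c(A = , B = )` with
#'   `A = mu_A / (mu_A + mu_B)`; `c(A = 1, B = 0)` under the single-strain
#'   flag.
#' @export
strain_abundance <- function(model) {
  if (isTRUE(model$single_strain)) return(c(A = 1, B = 0))
  tot <- model$mu_A + model$mu_B
  c(A = model$mu_A / tot, B = model$mu_B / tot)
}
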