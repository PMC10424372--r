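#' Covariate-adjusted logistic association for one variant
#'
#' Fits `status ~ dosage + covariates` by maximum likelihood (iteratively
#' reweighted least squares via [stats::glm()]), reporting the per-allele
#' log odds ratio with its Wald standard error, odds ratio with 95%
#' confidence interval (normal multiplier 1.959964) and two-sided Wald
#' p-value. Complete or quasi-separation (diverging `|beta| > 15` or
#' fitted probabilities at 0/1) is flagged with a warning rather than
#' returned silently.
#'
#' @param dosage Per-sample effect-allele dosage (0/1/2; `NA` dropped).
#' @param status Case indicator (0/1 or logical).
#' @param covariates Optional data frame or matrix of covariates; must be
#'   full rank together with the intercept.
#' @param snp,study,effect_allele Identifiers carried into the result.
#' @return An object of class `assoc_fit`; use [generics::tidy()] for the
#'   one-row result tibble and [generics::glance()] for fit diagnostics.
#' @export
fit_logistic <- function(dosage, status, covariates = NULL, snp = "snp",
                         study = NA_character_,
                         effect_allele = NA_character_) {
  status <- as.integer(status)
  df <- data.frame(status = status, dosage = as.numeric(dosage))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$status == 1) < 1 || sum(df$status == 0) < 1) {
    stop("need at least one case and one control", call. = FALSE)
  }
  mm <- stats::model.matrix(~ ., data = df[, -1, drop = FALSE])
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    dep <- colnames(mm)[qr(mm)$pivot[-seq_len(qr_rank)]]
    stop("design matrix rank deficient; offending column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(status ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  beta <- co["dosage", "Estimate"]
  se <- co["dosage", "Std. Error"]
  separation <- sep_warn || abs(beta) > 15
  if (separation) {
    warning("possible complete or quasi-separation for `", snp,
            "`; estimate unreliable", call. = FALSE)
  }
  z <- 1.959964
  maf <- mean(df$dosage) / 2
  result <- tibble::tibble(
    snp = snp,
    n_cases = sum(df$status == 1),
    n_controls = sum(df$status == 0),
    effect_allele = effect_allele,
    maf = min(maf, 1 - maf),
    beta = beta, se = se,
    or = exp(beta),
    ci_lower = exp(beta - z * se),
    ci_upper = exp(beta + z * se),
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    study = study,
    separation = separation
  )
  structure(list(result = result, fit = fit), class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  r <- x$result
  cat(sprintf("<assoc_fit> %s: OR = %.3f (%.3f-%.3f), P = %.3g\n",
              r$snp, r$or, r$ci_lower, r$ci_upper, r$wald_p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_logistic
#' @param x An `assoc_fit`.
#' @param ... Unused.
#' @export
tidy.assoc_fit <- function(x, ...) x$result

#' @rdname fit_logistic
#' @export
glance.assoc_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$fit$y),
    converged = x$fit$converged,
    separation = x$result$separation,
    logLik = as.numeric(stats::logLik(x$fit)),
    AIC = stats::AIC(x$fit),
    deviance = stats::deviance(x$fit)
  )
}

#' Vectorised multi-variant logistic scan
#'
#' Fits the per-variant logistic model `status ~ dosage + covariates` for
#' every column of a dosage matrix simultaneously with a blocked Newton
#' solver sharing the covariate matrix, giving genome-scale Wald statistics
#' orders of magnitude faster than per-variant [stats::glm()] calls (with
#' which it agrees to the convergence tolerance).
#'
#' @param G `n x m` dosage matrix (no missing values), columns named by
#'   variant id.
#' @param status Case indicator of length `n`.
#' @param covariates Optional `n x c` numeric matrix / data frame.
#' @param max_iter Maximum Newton iterations (default 25).
#' @param tol Convergence tolerance on the maximum absolute score
#'   (default 1e-8).
#' @return A tibble with columns `snp`, `beta`, `se`, `or`, `ci_lower`,
#'   `ci_upper`, `wald_p`, `converged`, `separation`.
#' @export
logistic_scan <- function(G, status, covariates = NULL, max_iter = 25,
                          tol = 1e-8) {
  G <- as.matrix(G)
  if (anyNA(G)) stop("dosage matrix must be complete", call. = FALSE)
  y <- as.numeric(status)
  n <- nrow(G)
  m <- ncol(G)
  X <- if (is.null(covariates)) matrix(numeric(0), n, 0) else {
    x <- as.matrix(as.data.frame(covariates))
    storage.mode(x) <- "double"
    x
  }
  nc <- ncol(X)
  p <- 2L + nc
  B <- matrix(0, p, m)
  B[1, ] <- stats::qlogis(mean(y))
  converged <- rep(FALSE, m)
  separation <- rep(FALSE, m)
  active <- seq_len(m)
  for (it in seq_len(max_iter)) {
    if (length(active) == 0) break
    Ga <- G[, active, drop = FALSE]
    ma <- length(active)
    eta <- matrix(B[1, active], n, ma, byrow = TRUE) +
      Ga * matrix(B[2, active], n, ma, byrow = TRUE)
    if (nc > 0) eta <- eta + X %*% B[3:p, active, drop = FALSE]
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    U <- matrix(0, p, ma)
    U[1, ] <- colSums(r)
    U[2, ] <- colSums(Ga * r)
    if (nc > 0) U[3:p, ] <- crossprod(X, r)
    # unique entries of the per-variant information matrices
    I11 <- colSums(w)
    I12 <- colSums(w * Ga)
    I22 <- colSums(w * Ga * Ga)
    I1k <- if (nc > 0) crossprod(X, w) else NULL          # c x ma
    I2k <- if (nc > 0) crossprod(X, w * Ga) else NULL     # c x ma
    Ikl <- if (nc > 0) lapply(seq_len(nc), function(k)
      crossprod(X, w * X[, k])) else NULL                 # list of c x ma
    for (a in seq_len(ma)) {
      s <- active[a]
      A <- matrix(0, p, p)
      A[1, 1] <- I11[a]; A[1, 2] <- A[2, 1] <- I12[a]; A[2, 2] <- I22[a]
      if (nc > 0) {
        A[1, 3:p] <- A[3:p, 1] <- I1k[, a]
        A[2, 3:p] <- A[3:p, 2] <- I2k[, a]
        for (k in seq_len(nc)) A[3:p, 2 + k] <- Ikl[[k]][, a]
      }
      step <- tryCatch(solve(A, U[, a]), error = function(e) NULL)
      if (is.null(step)) {
        separation[s] <- TRUE
        next
      }
      B[, s] <- B[, s] + step
      if (abs(B[2, s]) > 15) separation[s] <- TRUE
      else if (max(abs(U[, a])) < tol) converged[s] <- TRUE
    }
    active <- which(!converged & !separation)
  }
  # standard errors from the observed information at the final estimate
  eta <- matrix(B[1, ], n, m, byrow = TRUE) +
    G * matrix(B[2, ], n, m, byrow = TRUE)
  if (nc > 0) eta <- eta + X %*% B[3:p, , drop = FALSE]
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  I11 <- colSums(w); I12 <- colSums(w * G); I22 <- colSums(w * G * G)
  I1k <- if (nc > 0) crossprod(X, w) else NULL
  I2k <- if (nc > 0) crossprod(X, w * G) else NULL
  Ikl <- if (nc > 0) lapply(seq_len(nc), function(k)
    crossprod(X, w * X[, k])) else NULL
  se <- rep(NA_real_, m)
  for (s in seq_len(m)) {
    A <- matrix(0, p, p)
    A[1, 1] <- I11[s]; A[1, 2] <- A[2, 1] <- I12[s]; A[2, 2] <- I22[s]
    if (nc > 0) {
      A[1, 3:p] <- A[3:p, 1] <- I1k[, s]
      A[2, 3:p] <- A[3:p, 2] <- I2k[, s]
      for (k in seq_len(nc)) A[3:p, 2 + k] <- Ikl[[k]][, s]
    }
    v <- tryCatch(solve(A)[2, 2], error = function(e) NA_real_)
    se[s] <- sqrt(v)
  }
  beta <- B[2, ]
  z <- 1.959964
  tibble::tibble(
    snp = colnames(G) %||% paste0("snp", seq_len(m)),
    beta = beta, se = se, or = exp(beta),
    ci_lower = exp(beta - z * se), ci_upper = exp(beta + z * se),
    wald_p = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged, separation = separation
  )
}

#' Associate panel variants with a case-control phenotype
#'
#' @param panel A [haplotype_panel()].
#' @param pheno Phenotype tibble with columns `sample`, `status` and any
#'   covariate columns named in `covariates`.
#' @param snps Variant ids to test (default: all panel variants).
#' @param covariates Character vector of covariate column names in `pheno`.
#' @param engine `"glm"` for per-variant [fit_logistic()] (full
#'   diagnostics) or `"scan"` for the vectorised [logistic_scan()].
#' @param study Study label carried into results.
#' @return A tibble of per-variant association results, including `pos`.
#' @export
assoc_scan <- function(panel, pheno, snps = NULL,
                       covariates = character(0),
                       engine = c("scan", "glm"), study = NA_character_) {
  engine <- match.arg(engine)
  if (is.null(snps)) snps <- panel$variants$id
  idx <- match(snps, panel$variants$id)
  if (anyNA(idx)) {
    stop("variant(s) not in panel: ",
         paste(utils::head(snps[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  d <- dosages(panel)[pheno$sample, snps, drop = FALSE]
  X <- if (length(covariates) > 0) pheno[, covariates, drop = FALSE] else NULL
  if (engine == "scan") {
    d[is.na(d)] <- 0L
    res <- logistic_scan(d, pheno$status, covariates = X)
  } else {
    res <- dplyr::bind_rows(lapply(seq_along(snps), function(j) {
      tidy(fit_logistic(d[, j], pheno$status, covariates = X,
                        snp = snps[j], study = study,
                        effect_allele = panel$variants$alt[idx[j]]))
    }))
  }
  res$pos <- panel$variants$pos[idx][match(res$snp, snps)]
  res$study <- study
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Linkage disequilibrium from dosages or haplotypes
#'
#' `ld_r2()` is the squared Pearson correlation of dosage vectors
#' (composite LD, valid without phase); `ld_matrix()` computes it pairwise
#' for a dosage matrix; `ld_dprime()` computes the normalised
#' disequilibrium coefficient `|D| / Dmax` from phased haplotype vectors.
#' Monomorphic input gives r2 = 0 with a message (the pair carries no
#' pruning information).
#'
#' @param g1,g2 Dosage vectors over the same samples.
#' @return Squared correlation in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) {
    message("monomorphic variant in LD computation: r2 set to 0")
    return(0)
  }
  stats::cor(g1[ok], g2[ok])^2
}

#' @rdname ld_r2
#' @param G `n x m` dosage matrix with variant-id column names.
#' @export
ld_matrix <- function(G) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    r <- suppressWarnings(stats::cor(G, use = "pairwise.complete.obs"))^2
  } else {
    z <- scale(G)  # monomorphic columns become NaN and are zeroed below
    r <- (crossprod(z) / (nrow(G) - 1))^2
  }
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}

#' @rdname ld_r2
#' @param h1,h2 Phased haplotype allele vectors (0/1) over the same
#'   haplotypes.
#' @export
ld_dprime <- function(h1, h2) {
  ok <- !is.na(h1) & !is.na(h2)
  h1 <- h1[ok]; h2 <- h2[ok]
  pa <- mean(h1); pb <- mean(h2)
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    message("monomorphic haplotype in D' computation: returning 0")
    return(0)
  }
  pab <- mean(h1 == 1 & h2 == 1)
  d <- pab - pa * pb
  dmax <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb) else
    min(pa * pb, (1 - pa) * (1 - pb))
  abs(d) / dmax
}

#' Greedy LD pruning of association results
#'
#' Results are visited by ascending Wald p-value (ties broken by
#' position); each visited variant still unpruned is kept and every
#' remaining variant in LD with it (`r2 > r2_threshold`) is removed, so in
#' each LD block the variant with the lowest association p-value survives.
#'
#' @param results Association tibble with columns `snp`, `wald_p` and
#'   optionally `pos`.
#' @param ld Square r2 matrix with dimnames covering all result variants.
#' @param r2_threshold Pruning threshold (default 0.5).
#' @return The kept subset of `results`, in the visiting order.
#' @export
greedy_prune <- function(results, ld, r2_threshold = 0.5) {
  snps <- results$snp
  if (!all(snps %in% rownames(ld))) {
    stop("LD matrix lacks entries for: ",
         paste(utils::head(setdiff(snps, rownames(ld))), collapse = ", "),
         call. = FALSE)
  }
  pos <- if ("pos" %in% names(results)) results$pos else seq_along(snps)
  ord <- order(results$wald_p, pos)
  ld_idx <- match(snps, rownames(ld))
  state <- integer(length(snps))  # 0 undecided, 1 kept, -1 removed
  for (i in ord) {
    if (state[i] == -1L) next
    state[i] <- 1L
    hit <- ld[ld_idx[i], ld_idx] > r2_threshold & state == 0L
    state[hit] <- -1L
  }
  results[order(results$wald_p, pos)[state[ord] == 1L], , drop = FALSE]
}

#' Count independent variants at an r2 threshold
#'
#' Greedy construction in position order: a variant is counted when its r2
#' with every already-counted variant is below `r2_threshold`. The count is
#' the effective number of independent tests used by
#' [bonferroni_threshold()].
#'
#' @param snps Variant ids, in genomic order (or any fixed order).
#' @param ld Square r2 matrix covering `snps`.
#' @param r2_threshold Independence threshold (default 0.8).
#' @return Integer count `m`.
#' @export
count_independent <- function(snps, ld, r2_threshold = 0.8) {
  if (!all(snps %in% rownames(ld))) {
    stop("LD matrix lacks entries for some variants", call. = FALSE)
  }
  idx <- match(snps, rownames(ld))
  kept <- integer(0)
  for (i in idx) {
    if (length(kept) == 0 || all(ld[i, kept] < r2_threshold)) {
      kept <- c(kept, i)
    }
  }
  length(kept)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param m Number of independent tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (any(m < 1)) stop("`m` must be >= 1", call. = FALSE)
  alpha / m
}

#' Genomic inflation factor
#'
#' Lambda is the median association chi-square statistic divided by the
#' null median of a 1-df chi-square (0.4549364). Values near 1 indicate no
#' systematic inflation; p-values are converted through the upper-tail
#' inverse chi-square.
#'
#' @param p Vector of association p-values (used when `chisq` is `NULL`).
#' @param chisq Vector of 1-df chi-square statistics.
#' @return Lambda.
#' @export
genomic_lambda <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p) || length(p) == 0) {
      stop("supply `p` or `chisq`", call. = FALSE)
    }
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  if (length(chisq) == 0) stop("empty input", call. = FALSE)
  if (length(chisq) < 100) {
    warning("fewer than 100 statistics: lambda estimate is unstable")
  }
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Cross-study effect-direction concordance
#'
#' A variant passes when every study reports `p < alpha` and all effect
#' estimates share the same sign for the same effect allele (the
#' replication rule used when only summary statistics are available).
#' Mismatched effect alleles raise an error: alleles are never flipped
#' silently.
#'
#' @param stats_tbl Per-study summary tibble with columns `snp`, `study`,
#'   `beta`, `p` and optionally `effect_allele`.
#' @param alpha Per-study significance level (default 0.05).
#' @return A tibble with one row per variant: `snp`, `n_studies`, `pass`.
#' @export
concordance_filter <- function(stats_tbl, alpha = 0.05) {
  stats_tbl %>%
    dplyr::group_by(.data$snp) %>%
    dplyr::group_modify(function(d, key) {
      if ("effect_allele" %in% names(d) &&
          length(unique(d$effect_allele)) > 1) {
        stop("effect alleles differ across studies for `", key$snp,
             "`; align alleles before filtering", call. = FALSE)
      }
      if (nrow(d) < 2) {
        stop("concordance requires >= 2 studies per variant", call. = FALSE)
      }
      pass <- all(d$p < alpha) &&
        (all(d$beta > 0) || all(d$beta < 0))
      tibble::tibble(n_studies = nrow(d), pass = pass)
    }) %>%
    dplyr::ungroup()
}
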