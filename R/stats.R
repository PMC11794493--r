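# Behavioral and neural statistics: single-pass outlier exclusion, paired
# t tests with Cohen's d_z, Greenhouse-Geisser epsilon, the 3 x 2 (and
# general two-factor) repeated-measures ANOVA with GG-corrected p and
# partial eta-squared, and simple-effects decomposition.

#' Single-pass SD-based outlier exclusion
#'
#' Removes values farther than \code{k} standard deviations from the mean,
#' with mean and SD computed once from the full sample (no iteration).
#'
#' @param values numeric vector (subject-level measures).
#' @param k SD multiplier (default 3; \code{Inf} disables).
#' @return list: \code{values} (retained), \code{removed} (indices into the
#'   input), \code{bounds} (the acceptance interval used).
#' @export
excludeOutliers <- function(values, k = 3) {
  stopifnot(k > 0, length(values) >= 3L)
  m <- mean(values)
  s <- sd(values)
  bad <- if (is.finite(k) && s > 0) which(abs(values - m) > k * s) else integer(0)
  keep <- if (length(bad)) values[-bad] else values
  list(values = keep, removed = bad,
       bounds = c(lower = m - k * s, upper = m + k * s))
}

#' Paired-samples t test
#'
#' Two-sided paired t on subject-matched vectors, reporting Cohen's
#' \code{d_z = mean(d)/sd(d)} and per-group descriptives. Degenerate cases
#' are handled explicitly: identical pairs give t = 0, p = 1; zero-variance
#' nonzero differences give an infinite t flagged with p = 0.
#'
#' @param x,y numeric vectors of equal length (n >= 2), paired by subject.
#' @return data.frame row: \code{t}, \code{df}, \code{p}, \code{cohens_dz},
#'   \code{mean_x}, \code{sd_x}, \code{mean_y}, \code{sd_y}, \code{mean_diff}.
#' @export
#' @examples
#' pairedT(c(1, 2, 3), c(2, 4, 3))  # t = -sqrt(3), df = 2
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2L) stop("paired t needs at least 2 pairs")
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      tval <- 0; p <- 1; dz <- 0
    } else {
      tval <- sign(mean(d)) * Inf; p <- 0; dz <- sign(mean(d)) * Inf
    }
  } else {
    tt <- t.test(x, y, paired = TRUE)
    tval <- unname(tt$statistic)
    p <- tt$p.value
    dz <- mean(d) / sdd
  }
  data.frame(t = tval, df = n - 1L, p = p, cohens_dz = dz,
             mean_x = mean(x), sd_x = sd(x),
             mean_y = mean(y), sd_y = sd(y), mean_diff = mean(d))
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor from the covariance matrix of the k
#' within-subject condition measures: with lambda the nonzero eigenvalues of
#' the double-centered covariance (equivalently the covariance of any
#' orthonormal contrast set), \code{epsilon = (sum lambda)^2 / ((k - 1) *
#' sum lambda^2)}, bounded in [1/(k-1), 1].
#'
#' @param cov k x k symmetric positive semi-definite covariance matrix
#'   (k >= 2), or the contrast covariance together with \code{df} when the
#'   contrasts are supplied directly.
#' @param contrasts optional k x (k-1)-column orthonormal contrast matrix;
#'   default: any orthonormal basis of the centering space (epsilon is
#'   invariant to the choice).
#' @return epsilon (scalar).
#' @export
ggEpsilon <- function(cov, contrasts = NULL) {
  cov <- as.matrix(cov)
  k <- nrow(cov)
  stopifnot(k >= 2L, ncol(cov) == k)
  if (max(abs(cov)) == 0) stop("zero covariance matrix: epsilon undefined")
  if (is.null(contrasts)) {
    # orthonormal basis orthogonal to the unit vector
    contrasts <- qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
  }
  M <- contrasts
  S <- t(M) %*% cov %*% M
  lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  d <- ncol(M)
  eps <- sum(lam)^2 / (d * sum(lam^2))
  min(1, max(1 / d, eps))
}

# Orthonormal polynomial-free contrast basis for a factor with k levels.
orthoContrasts <- function(k) {
  qr.Q(qr(cbind(rep(1, k), diag(k))))[, 2:k, drop = FALSE]
}

#' Two-factor repeated-measures ANOVA with GG correction
#'
#' Fully within-subject A x B ANOVA (the study design is 3 sensory channels
#' x 2 music types). Sums of squares are partitioned subject-wise via
#' \code{stats::aov} with \code{Error(subject/(A*B))} strata, so each effect
#' is tested against its own subject-by-effect error term. For every effect
#' the Greenhouse-Geisser epsilon is estimated from the covariance of the
#' effect's orthonormal contrast scores across subjects (epsilon = 1
#' trivially for 1-df effects), and the GG-corrected p uses the deflated
#' degrees of freedom. Partial eta-squared is \code{SS_effect / (SS_effect +
#' SS_error)}.
#'
#' @param table data.frame with columns \code{subject}, \code{channelType},
#'   \code{musicType}, \code{value}: one value per subject x cell (use
#'   \code{\link{cellMeans}} to collapse trials).
#' @param factorA,factorB column names of the two within-subject factors.
#' @return data.frame with one row per effect (A, B, A:B): \code{SS},
#'   \code{df}, \code{SS_error}, \code{df_error}, \code{F}, \code{p},
#'   \code{gg_epsilon}, \code{p_gg}, \code{eta2p}.
#' @export
rmAnova <- function(table, factorA = "channelType", factorB = "musicType") {
  need <- c("subject", factorA, factorB, "value")
  stopifnot(all(need %in% names(table)))
  tab <- table
  tab$subject <- factor(tab$subject)
  tab$A <- factor(tab[[factorA]])
  tab$B <- factor(tab[[factorB]])
  a <- nlevels(tab$A); b <- nlevels(tab$B)
  # completeness check
  cnt <- table(tab$subject, tab$A, tab$B)
  if (any(cnt != 1L)) {
    badSubj <- dimnames(cnt)[[1]][apply(cnt != 1L, 1, any)]
    stop("incomplete or duplicated cells for subject(s): ",
         paste(badSubj, collapse = ", "))
  }
  # a single-level factor degrades gracefully to the one-way design
  if (a == 1L || b == 1L) {
    f <- if (a == 1L) "B" else "A"
    fname <- if (a == 1L) factorB else factorA
    tab$G <- tab[[if (a == 1L) "B" else "A"]]
    fit <- aov(value ~ G + Error(subject / G), data = tab)
    st <- summary(fit)[["Error: subject:G"]][[1]]
    i <- match("G", trimws(rownames(st)))
    er <- match("Residuals", trimws(rownames(st)))
    eps <- epsForEffect(tab, "G", NULL)
    Fv <- (st[i, "Sum Sq"] / st[i, "Df"]) / (st[er, "Sum Sq"] / st[er, "Df"])
    return(data.frame(
      effect = fname, SS = st[i, "Sum Sq"], df = st[i, "Df"],
      SS_error = st[er, "Sum Sq"], df_error = st[er, "Df"], F = Fv,
      p = pf(Fv, st[i, "Df"], st[er, "Df"], lower.tail = FALSE),
      gg_epsilon = eps,
      p_gg = pf(Fv, st[i, "Df"] * eps, st[er, "Df"] * eps, lower.tail = FALSE),
      eta2p = st[i, "Sum Sq"] / (st[i, "Sum Sq"] + st[er, "Sum Sq"]),
      stringsAsFactors = FALSE))
  }
  fit <- aov(value ~ A * B + Error(subject / (A * B)), data = tab)
  sm <- summary(fit)
  pull <- function(stratum, effect) {
    st <- sm[[stratum]][[1]]
    i <- match(effect, trimws(rownames(st)))
    er <- match("Residuals", trimws(rownames(st)))
    c(SS = st[i, "Sum Sq"], df = st[i, "Df"],
      SSe = st[er, "Sum Sq"], dfe = st[er, "Df"])
  }
  effects <- list(
    list(name = factorA, stratum = "Error: subject:A", effect = "A",
         eps = epsForEffect(tab, "A", NULL)),
    list(name = factorB, stratum = "Error: subject:B", effect = "B",
         eps = epsForEffect(tab, "B", NULL)),
    list(name = paste0(factorA, ":", factorB), stratum = "Error: subject:A:B",
         effect = "A:B", eps = epsForEffect(tab, "A", "B"))
  )
  totalSS <- sum((tab$value - mean(tab$value))^2)
  rows <- lapply(effects, function(e) {
    v <- pull(e$stratum, e$effect)
    if (v["SS"] <= 1e-12 * max(totalSS, 1)) {
      # no condition variation at all: define F = 0 rather than 0/0
      v["SS"] <- 0
      Fv <- 0
    } else {
      Fv <- (v["SS"] / v["df"]) / (v["SSe"] / v["dfe"])
    }
    p <- pf(Fv, v["df"], v["dfe"], lower.tail = FALSE)
    pGG <- pf(Fv, v["df"] * e$eps, v["dfe"] * e$eps, lower.tail = FALSE)
    data.frame(effect = e$name, SS = unname(v["SS"]), df = unname(v["df"]),
               SS_error = unname(v["SSe"]), df_error = unname(v["dfe"]),
               F = unname(Fv), p = unname(p), gg_epsilon = e$eps,
               p_gg = unname(pGG),
               eta2p = unname(v["SS"] / (v["SS"] + v["SSe"])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Epsilon for a main effect (factor f, other averaged out) or, with both
# given, for the interaction (Kronecker contrast basis on the a*b cells).
epsForEffect <- function(tab, f, g = NULL) {
  if (is.null(g)) {
    m <- tapply(tab$value, list(tab$subject, tab[[f]]), mean)
    k <- ncol(m)
    if (k == 2L) return(1)
    S <- stats::cov(m)
    M <- orthoContrasts(k)
    if (max(abs(t(M) %*% S %*% M)) < 1e-12 * max(max(abs(S)), 1))
      return(1)  # no within-subject variation: sphericity holds trivially
    ggEpsilon(S, M)
  } else {
    cellKey <- interaction(tab[[f]], tab[[g]], lex.order = TRUE)
    m <- tapply(tab$value, list(tab$subject, cellKey), mean)
    a <- nlevels(factor(tab[[f]])); b <- nlevels(factor(tab[[g]]))
    M <- kronecker(orthoContrasts(a), orthoContrasts(b))
    d <- (a - 1) * (b - 1)
    if (d == 1L) return(1)
    S <- stats::cov(m)
    if (max(abs(t(M) %*% S %*% M)) < 1e-12 * max(max(abs(S)), 1))
      return(1)
    ggEpsilon(S, M)
  }
}

#' @rdname rmAnova
#' @export
rmAnova3x2 <- rmAnova

#' Simple-effects decomposition
#'
#' Pairwise paired t tests of one within-subject factor at each fixed level
#' of the other, on subject-level cell means. P values are reported
#' uncorrected by default (with a Holm/FDR adjustment option, flagged in the
#' output).
#'
#' @param table subject x cell table as for \code{\link{rmAnova}}.
#' @param factor the factor whose levels are compared (e.g.
#'   \code{"channelType"}).
#' @param within the factor whose levels are conditioned on.
#' @param adjust \code{"none"} (default), \code{"holm"} or \code{"fdr"}.
#' @return data.frame: one row per (conditioning level, level pair) with the
#'   paired-t columns plus \code{p_adjusted} and \code{adjust}.
#' @export
simpleEffects <- function(table, factor = "channelType",
                          within = "musicType", adjust = "none") {
  stopifnot(all(c("subject", factor, within, "value") %in% names(table)))
  levsW <- unique(table[[within]])
  levsF <- unique(table[[factor]])
  if (length(levsF) < 2L) stop("need at least 2 levels to compare")
  out <- list()
  for (w in levsW) {
    sub <- table[table[[within]] == w, ]
    prs <- utils::combn(levsF, 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      x <- sub$value[sub[[factor]] == pr[1]][order(sub$subject[sub[[factor]] == pr[1]])]
      y <- sub$value[sub[[factor]] == pr[2]][order(sub$subject[sub[[factor]] == pr[2]])]
      cbind(data.frame(at = w, level_1 = pr[1], level_2 = pr[2],
                       stringsAsFactors = FALSE),
            pairedT(x, y))
    })
    block <- do.call(rbind, rows)
    block$p_adjusted <- p.adjust(block$p, method = adjust)
    out[[w]] <- block
  }
  res <- do.call(rbind, out)
  res$adjust <- adjust
  rownames(res) <- NULL
  res
}

#' Band-wise network-metric comparison between conditions
#'
#' Subject-level paired t tests of each network metric (and mean WPLI)
#' between two music types, per band — the neural headline analysis. By
#' default p values are uncorrected, mirroring per-band reporting practice,
#' and a multiplicity note is attached; FDR correction is available.
#'
#' @param metricsTable data.frame with columns \code{subject}, \code{band},
#'   \code{condition} plus metric columns (as built from
#'   \code{\link{metricsRow}}).
#' @param metrics metric column names to test.
#' @param conditionA,conditionB the two condition labels to contrast
#'   (A minus B).
#' @param adjust \code{"none"} (default) or \code{"fdr"}.
#' @return data.frame, one row per band x metric.
#' @export
compareNetworkMetrics <- function(metricsTable,
                                  metrics = c("strength", "global_efficiency",
                                              "local_efficiency",
                                              "char_path_length"),
                                  conditionA = "nostalgic",
                                  conditionB = "non-nostalgic",
                                  adjust = "none") {
  out <- list()
  for (bn in unique(metricsTable$band)) {
    for (m in metrics) {
      a <- metricsTable[metricsTable$band == bn & metricsTable$condition == conditionA, ]
      b <- metricsTable[metricsTable$band == bn & metricsTable$condition == conditionB, ]
      a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
      stopifnot(identical(a$subject, b$subject))
      row <- cbind(data.frame(band = bn, metric = m, stringsAsFactors = FALSE),
                   pairedT(a[[m]], b[[m]]))
      out[[paste(bn, m)]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$p_adjusted <- p.adjust(res$p, method = if (adjust == "none") "none" else "fdr")
  res$adjust <- adjust
  rownames(res) <- NULL
  attr(res, "note") <- paste(
    "Per-band, per-metric tests are reported uncorrected by default;",
    "with 5 bands x 4 metrics consider the fdr option.")
  res
}
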