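# Rank-based robustness statistics over scan outcomes.

#' Map an unordered pair of run classes to a robustness rank
#'
#' The up/down outcome pair of a scanned parameter is ranked on a 1-6 scale:
#' 0/0 = 1, 0/1 = 2, 0/2 = 3, 1/1 = 4, 1/2 = 5, 2/2 = 6. The pair is
#' unordered (1/0 ranks as 0/1).
#'
#' @param up,down Run classes in \{0, 1, 2\} (vectorized).
#' @return Integer rank(s) in 1..6.
#' @export
pairRank <- function(up, down) {
  stopifnot(all(up %in% 0:2), all(down %in% 0:2))
  lo <- pmin(up, down); hi <- pmax(up, down)
  key <- paste(lo, hi)
  map <- c("0 0" = 1L, "0 1" = 2L, "0 2" = 3L, "1 1" = 4L, "1 2" = 5L,
           "2 2" = 6L)
  unname(map[key])
}

#' Rank event robustness across one or more scans
#'
#' Each scan contributes one up/down code pair per event; pairs map to ranks
#' via [pairRank()] and the per-event score is the mean rank across scans.
#' Events are partitioned into `critical` (some scan produced a class-0
#' failure), `robust` (every pair is 2/2) and `intermediate`.
#'
#' @param ... One or more `cyclephase_scan` objects (or their `pairs` data
#'   frames with columns `event`, `up`, `down`, optionally `link`).
#' @param labels Optional scan labels (defaults to scan1, scan2, ...).
#' @return A data frame: `event`, `link`, one `rank_<label>` column per
#'   scan, `mean_rank`, `class`.
#' @export
rankEvents <- function(..., labels = NULL) {
  scans <- lapply(list(...), function(s)
    if (inherits(s, "cyclephase_scan")) s$pairs else s)
  stopifnot(length(scans) >= 1)
  if (is.null(labels)) labels <- paste0("scan", seq_along(scans))
  base <- scans[[1]][, c("event", "link")]
  ranks <- matrix(NA_real_, nrow(base), length(scans),
                  dimnames = list(NULL, paste0("rank_", labels)))
  anyfail <- logical(nrow(base)); all22 <- rep(TRUE, nrow(base))
  for (j in seq_along(scans)) {
    s <- scans[[j]][match(base$event, scans[[j]]$event), ]
    if (anyNA(s$up) || anyNA(s$down))
      stop("every event needs both directions scored in every scan",
           call. = FALSE)
    ranks[, j] <- pairRank(s$up, s$down)
    anyfail <- anyfail | s$up == 0 | s$down == 0
    all22 <- all22 & s$up == 2 & s$down == 2
  }
  cls <- ifelse(anyfail, "critical", ifelse(all22, "robust", "intermediate"))
  out <- cbind(base, as.data.frame(ranks),
               data.frame(mean_rank = rowMeans(ranks), class = cls,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Global F test and unequal-variance pairwise comparisons over rank scores
#'
#' One-way fixed-effects F statistic over event groups (e.g. per-regulator
#' families), followed by Tamhane's T2 multiple comparisons: pairwise Welch
#' t tests with Sidak-adjusted p values, which do not assume equal group
#' variances. Rank scores are ordinal; the parametric F over them is the
#' conventional omnibus screen and is flagged as such.
#'
#' @param scores Numeric vector of rank scores.
#' @param groups Factor/character vector of group membership.
#' @return List: `F` (statistic), `df` (c(between, within)), `p_value`,
#'   `pairwise` (data frame with Welch t, df, raw and Sidak-adjusted p per
#'   group pair), `note` (ordinal-data caveat). When all scores are equal
#'   the F statistic is reported as `NaN` with an explanatory note.
#' @export
omnibusTest <- function(scores, groups) {
  groups <- factor(groups)
  stopifnot(length(scores) == length(groups))
  if (nlevels(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  if (any(tabulate(groups) < 2))
    stop("need at least two observations per group", call. = FALSE)
  note <- "F test over ordinal rank scores; interpret as an omnibus screen"
  df1 <- nlevels(groups) - 1L
  df2 <- length(scores) - nlevels(groups)
  if (var(scores) == 0) {
    Fstat <- NaN
    p <- NA_real_
    note <- paste(note, "(degenerate input: all scores equal, F undefined)")
  } else {
    fit <- stats::oneway.test(scores ~ groups, var.equal = TRUE)
    Fstat <- unname(fit$statistic)
    p <- fit$p.value
  }

  # Tamhane's T2: pairwise Welch t tests with Sidak family correction
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  m <- ncol(combs)
  pw <- lapply(seq_len(m), function(i) {
    a <- scores[groups == combs[1, i]]; b <- scores[groups == combs[2, i]]
    if (var(a) == 0 && var(b) == 0) {
      tt <- ifelse(mean(a) == mean(b), 0, sign(mean(a) - mean(b)) * Inf)
      df <- length(a) + length(b) - 2
      praw <- ifelse(tt == 0, 1, 0)
    } else {
      ht <- stats::t.test(a, b, var.equal = FALSE)
      tt <- unname(ht$statistic); df <- unname(ht$parameter)
      praw <- ht$p.value
    }
    data.frame(group1 = combs[1, i], group2 = combs[2, i],
               diff = mean(a) - mean(b), t = tt, df = df, p = praw)
  })
  pw <- do.call(rbind, pw)
  pw$p_sidak <- pmin(1, 1 - (1 - pw$p)^m)
  list(F = Fstat, df = c(df1, df2), p_value = p, pairwise = pw, note = note)
}
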