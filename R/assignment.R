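# O(n^3) Hungarian algorithm (potentials + shortest augmenting paths) for a
# square cost matrix; returns the column assigned to each row.
hungarian_min <- function(a) {
  n <- nrow(a)
  stopifnot(ncol(a) == n, n >= 1)
  u <- numeric(n)
  v <- numeric(n + 1)     # index 1 is a virtual column
  p <- integer(n + 1)     # p[j + 1] = row currently matched to column j
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    way <- integer(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq(2L, n + 1L)) {
        if (used[j]) next
        cur <- a[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  match <- integer(n)
  for (j in seq(2L, n + 1L)) if (p[j] > 0L) match[p[j]] <- j - 1L
  match
}

# Maximum-sum one-to-one assignment for a rectangular matrix with
# nrow(p) <= ncol(p); dummy zero rows pad the matrix square.
assign_max <- function(p) {
  r <- nrow(p); c <- ncol(p)
  stopifnot(r >= 1, r <= c)
  cost <- matrix(0, c, c)
  cost[seq_len(r), ] <- max(p) - p
  hungarian_min(cost)[seq_len(r)]
}

#' Match a group of tracklets to training classes
#'
#' Given the matrix of predicted class probabilities for a group of tracklets
#' (rows) against the classes of a trained classifier (columns), finds the
#' one-to-one assignment maximizing the total probability via the Hungarian
#' algorithm. The assignment as a whole is accepted only if every selected
#' probability exceeds `1/N` (with `N` identities); selected probabilities
#' below `Thr_p` are flagged as possible matching errors for review. When
#' there are fewer tracklets than classes, the left-over columns are reported
#' as unmatched classes — the procedure used to single out an individual
#' present in the training video but absent from the test video.
#'
#' @param P numeric matrix of probabilities, rows = test tracklets, cols =
#'   classes, `nrow(P) <= ncol(P)`. Rows are renormalized to sum to 1.
#' @param N number of identities used in the `1/N` acceptance rule; defaults
#'   to `ncol(P)`.
#' @param Thr_p probability threshold below which an accepted match is
#'   flagged (default 0.60).
#' @return A list of class `zf_assignment`: `labels` (class index per row),
#'   `prob` (selected probability per row), `accepted`, `flagged_low_confidence`
#'   (row indices), `unmatched_classes`, `objective`.
#' @examples
#' P <- diag(3)
#' match_groups(P)$labels   # 1 2 3
#' @export
match_groups <- function(P, N = ncol(P), Thr_p = 0.60) {
  P <- as.matrix(P)
  if (length(P) == 0) stop("empty probability matrix", call. = FALSE)
  if (nrow(P) > ncol(P))
    stop("more test tracklets than classes (rows must be <= cols)",
         call. = FALSE)
  rs <- rowSums(P)
  if (any(rs <= 0)) stop("probability rows must have positive sums",
                         call. = FALSE)
  P <- P / rs
  labels <- assign_max(P)
  sel <- P[cbind(seq_len(nrow(P)), labels)]
  out <- list(
    labels = labels,
    prob = sel,
    accepted = all(sel > 1 / N),
    flagged_low_confidence = which(sel < Thr_p),
    unmatched_classes = setdiff(seq_len(ncol(P)), labels),
    objective = sum(sel))
  class(out) <- "zf_assignment"
  out
}

#' @export
print.zf_assignment <- function(x, ...) {
  cat(sprintf("Tracklet group assignment (%s)\n",
              if (x$accepted) "accepted" else "rejected by the 1/N rule"))
  cat("  labels:", paste(x$labels, collapse = " "), "\n")
  cat("  probabilities:", paste(sprintf("%.3f", x$prob), collapse = " "), "\n")
  if (length(x$unmatched_classes))
    cat("  unmatched classes:", paste(x$unmatched_classes, collapse = " "), "\n")
  if (length(x$flagged_low_confidence))
    cat("  flagged rows:", paste(x$flagged_low_confidence, collapse = " "), "\n")
  invisible(x)
}
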