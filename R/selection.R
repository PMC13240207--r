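#' Tajima's D for a set of haplotypes
#'
#' Contrasts mean pairwise diversity pi with the normalized segregating
#' site count S/a1:
#'
#'   D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))
#'
#' with the usual constants a1, a2, b1, b2, c1, c2, e1, e2 computed from
#' the haplotype count n.  pi is computed from the site frequency spectrum
#' (sum over sites of 2 j (n - j) / (n (n - 1))), which equals the mean of
#' all pairwise Hamming distances.  D is flagged undefined (NA) when S = 0
#' or n < 4.
#'
#' @param x a missing-free [haplotype_panel()] (all rows used) or a 0/1
#'   matrix, rows = haplotypes
#' @return an object of class `tajima_result`: `n`, `S`, `pi`, `D`,
#'   `undefined` flag, and the constant set
#' @export
tajimas_d <- function(x) {
  X <- if (inherits(x, "haplotype_panel")) x$alleles else x
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (anyNA(X)) stop("missing alleles; filter sites first", call. = FALSE)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 haplotypes", call. = FALSE)
  j <- colSums(X)
  seg <- j > 0L & j < n
  S <- sum(seg)
  pi <- sum(2 * j[seg] * (n - j[seg])) / (n * (n - 1))
  k <- tajima_constants(n)
  undefined <- S == 0L || n < 4L
  D <- if (undefined) NA_real_ else {
    v <- k$e1 * S + k$e2 * S * (S - 1)
    if (v <= 0) NA_real_ else (pi - S / k$a1) / sqrt(v)
  }
  structure(c(list(n = n, S = S, pi = pi, D = D,
                   undefined = undefined || is.na(D)), k),
            class = "tajima_result")
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("<tajima_result> n = %d, S = %d, pi = %.4f, D = %s\n",
              x$n, x$S, x$pi,
              if (x$undefined) "undefined" else sprintf("%.4f", x$D)))
  invisible(x)
}

#' Sliding-window Tajima's D with per-step averaging
#'
#' D is computed in physical windows of `window` bp advanced by `step` bp
#' across the scan region; the reported value at each step position is the
#' average of D over all windows covering that position (windows with
#' undefined D are excluded from the average).  `by = "sites"` instead
#' slides over site indices (window and step counted in segregating
#' sites).
#'
#' @param x a missing-free [haplotype_panel()]; supply the modern rows
#'   (e.g. via [subset_panel()]) — all rows of `x` enter the statistic
#' @param region `"chrom:start-end"` scan region; default the panel span
#' @param window window size (bp, or sites when `by = "sites"`)
#' @param step step size; the literal per-base reading is `step = 1`,
#'   the desk-scale default is 100 bp (equivalence tested)
#' @param by `"bp"` (default) or `"sites"`
#' @return data.frame(pos, D) of class `window_track`; zero rows (with a
#'   warning) when no window is polymorphic
#' @export
sliding_tajima <- function(x, region = NULL, window = 10000, step = 100,
                           by = c("bp", "sites")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "haplotype_panel"))
  if (anyNA(x$alleles)) stop("missing alleles; filter sites first", call. = FALSE)
  n <- n_haplotypes(x)
  pos <- x$sites$pos
  j <- colSums(x$alleles)
  seg <- j > 0L & j < n
  k <- tajima_constants(n)
  pic <- ifelse(seg, 2 * j * (n - j) / (n * (n - 1)), 0)  # per-site pi

  d_of <- function(S, pi) {
    if (S == 0L || n < 4L) return(NA_real_)
    v <- k$e1 * S + k$e2 * S * (S - 1)
    if (v <= 0) NA_real_ else (pi - S / k$a1) / sqrt(v)
  }

  if (by == "sites") {
    idx <- which(seg)
    if (length(idx) < window) {
      warning("fewer segregating sites than the window size")
      return(empty_track(window, step, by))
    }
    starts <- seq.int(1L, length(idx) - window + 1L, by = step)
    D <- vapply(starts, function(s) {
      cols <- idx[s:(s + window - 1L)]
      d_of(window, sum(pic[cols]))
    }, numeric(1L))
    out <- data.frame(pos = pos[idx[starts + (window - 1L) %/% 2L]], D = D)
    return(as_track(out, window, step, by))
  }

  reg <- if (is.null(region))
    list(chrom = x$sites$chrom[1L], start = min(pos), end = max(pos))
  else parse_region(region)
  if (window > reg$end - reg$start + 1)
    stop("window exceeds the scan region", call. = FALSE)
  starts <- seq.int(reg$start, reg$end - window + 1, by = step)
  # per-window S and pi via prefix sums over sites in position order
  o <- order(pos)
  cs_S <- c(0, cumsum(as.numeric(seg[o])))
  cs_pi <- c(0, cumsum(pic[o]))
  lo <- findInterval(starts - 1e-9, pos[o])            # sites with p >= start
  hi <- findInterval(starts + window - 1 + 1e-9, pos[o])  # p <= start+window-1
  Dw <- vapply(seq_along(starts), function(w) {
    d_of(cs_S[hi[w] + 1L] - cs_S[lo[w] + 1L],
         cs_pi[hi[w] + 1L] - cs_pi[lo[w] + 1L])
  }, numeric(1L))
  if (all(is.na(Dw))) {
    warning("no polymorphic window in the scan region")
    return(empty_track(window, step, by))
  }
  # average, at each step position, the D of every window covering it
  grid <- seq.int(reg$start, reg$end, by = step)
  cum_ok <- c(0, cumsum(!is.na(Dw)))
  cum_D <- c(0, cumsum(ifelse(is.na(Dw), 0, Dw)))
  Dg <- vapply(grid, function(p) {
    w1 <- findInterval(p - window, starts) + 1L     # first start > p - window
    w2 <- findInterval(p, starts)                   # last start <= p
    if (w2 < w1) return(NA_real_)
    ok <- cum_ok[w2 + 1L] - cum_ok[w1]
    if (ok == 0) NA_real_ else (cum_D[w2 + 1L] - cum_D[w1]) / ok
  }, numeric(1L))
  as_track(data.frame(pos = grid, D = Dg), window, step, by)
}

as_track <- function(df, window, step, by) {
  structure(df, class = c("window_track", "data.frame"),
            window = window, step = step, by = by)
}

empty_track <- function(window, step, by)
  as_track(data.frame(pos = numeric(), D = numeric()), window, step, by)
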