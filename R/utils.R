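# Shared helpers: timestamp handling and weighted least squares.

# Parse ISO-8601 local timestamps ("2015-05-01T16:00:00" or with a space).
# Stored as POSIXct in UTC; the package never does timezone arithmetic
# (single-site local clock).
.parseTime <- function(x) {
  x <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (any(is.na(out)))
    stop("unparseable ISO-8601 timestamp: ",
         paste(head(x[is.na(out)], 3), collapse = ", "))
  out
}

.formatTime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Fractional hour of day (0 <= h < 24).
.hourOfDay <- function(times) {
  lt <- as.POSIXlt(times, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Weighted least squares fit
#'
#' Minimises \eqn{\sum_s w_s (y_s - x_s'\beta)^2} by QR decomposition of the
#' row-scaled design. Accepts a matrix of responses (one column per fit
#' sharing the same design and weights).
#'
#' @param X numeric design matrix (n x k).
#' @param y numeric response vector of length n, or an n x m matrix.
#' @param w positive weights of length n (default: unweighted).
#' @return list with \code{coef} (k x m), \code{rssw} (weighted residual sum
#'   of squares per column), \code{fitted} (n x m) and \code{rank}.
#' @examples
#' X <- cbind(1, 1:4)
#' fit <- wlsFit(X, c(1, 3, 2, 5), w = c(1, 2, 1, 2))
#' fit$coef
#' @export
wlsFit <- function(X, y, w = rep(1, nrow(X))) {
  X <- as.matrix(X)
  y <- as.matrix(y)
  stopifnot(nrow(y) == nrow(X), length(w) == nrow(X), all(w > 0))
  sw <- sqrt(w)
  qrX <- qr(X * sw)
  beta <- qr.coef(qrX, y * sw)
  beta[is.na(beta)] <- 0
  fitted <- X %*% beta
  res <- y - fitted
  rssw <- colSums(w * res^2)
  list(coef = beta, rssw = rssw, fitted = fitted, rank = qrX$rank)
}

# Empirical permutation p-value with the +1 correction (never returns 0).
.permP <- function(nullGeq, nPerm) (1 + nullGeq) / (nPerm + 1)

# Deterministic child seed derived from a user seed (kept < 2^31).
.childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + 7L * as.integer(k)
}
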