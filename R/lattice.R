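#' Discrete velocity set descriptors
#'
#' Builds the D2Q9 or D3Q19 lattice descriptor: integer velocity vectors
#' \code{c_i}, quadrature weights \code{w_i}, squared sound speed
#' \code{cs2 = 1/3} and the opposite-direction map. The numbering follows the
#' Palabos convention (index 0 is the rest velocity; indices \code{1..q/2}
#' are the negatives of \code{q/2+1..q-1} in order), and the weights satisfy
#' the isotropy moment identities
#' \eqn{\sum w_i = 1}, \eqn{\sum w_i c_i = 0},
#' \eqn{\sum w_i c_{i\alpha} c_{i\beta} = c_s^2 \delta_{\alpha\beta}}.
#'
#' @param kind \code{"D2Q9"} or \code{"D3Q19"}.
#' @return object of class \code{"mf_lattice"}: list with \code{d}, \code{q},
#'   \code{c} (q x d integer matrix), \code{w} (length q), \code{cs2},
#'   \code{opp} (1-based opposite index map).
#' @examples
#' lat <- make_lattice("D2Q9")
#' colSums(lat$w * lat$c)      # zero first moment
#' @export
make_lattice <- function(kind = c("D2Q9", "D3Q19")) {
  kind <- match.arg(kind)
  if (kind == "D2Q9") {
    cvec <- rbind(c(0, 0),
                  c(-1, 1), c(-1, 0), c(-1, -1), c(0, -1),
                  c(1, -1), c(1, 0), c(1, 1), c(0, 1))
    w <- c(4 / 9, 1 / 36, 1 / 9, 1 / 36, 1 / 9, 1 / 36, 1 / 9, 1 / 36, 1 / 9)
  } else {
    neg <- rbind(c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1),
                 c(-1, -1, 0), c(-1, 1, 0), c(-1, 0, -1), c(-1, 0, 1),
                 c(0, -1, -1), c(0, -1, 1))
    cvec <- rbind(c(0, 0, 0), neg, -neg)
    w1 <- c(1 / 18, 1 / 18, 1 / 18, 1 / 36, 1 / 36, 1 / 36, 1 / 36, 1 / 36, 1 / 36)
    w <- c(1 / 3, w1, w1)
  }
  q <- nrow(cvec)
  opp <- integer(q)
  for (i in seq_len(q)) {
    opp[i] <- which(colSums(t(cvec) == -cvec[i, ]) == ncol(cvec))[1]
  }
  structure(list(kind = kind, d = ncol(cvec), q = q,
                 c = cvec, w = w, cs2 = 1 / 3, opp = opp),
            class = "mf_lattice")
}

#' @export
print.mf_lattice <- function(x, ...) {
  cat(sprintf("%s lattice: d = %d, q = %d, cs2 = 1/3\n", x$kind, x$d, x$q))
  invisible(x)
}
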