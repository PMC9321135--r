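#' Hydraulic resistance network
#'
#' A channel circuit in the electric-network analogy: nodes are junctions or
#' boundary terminals, edges are channel segments carrying a hydraulic
#' resistance \code{R_H} (Pa s/m^3). Boundary nodes fix either a pressure
#' (Pa) or an injected flow (m^3/s, positive into the network).
#'
#' @param edges data frame with columns \code{from}, \code{to} (node names)
#'   and \code{R} (> 0).
#' @param fixed_p named numeric vector of fixed node pressures.
#' @param fixed_q named numeric vector of injected node flows.
#' @return object of class \code{"mf_network"}.
#' @examples
#' net <- hydraulic_network(
#'   edges = data.frame(from = c("in", "j", "j"), to = c("j", "t", "b"),
#'                      R = c(1e12, 2e12, 2e12)),
#'   fixed_p = c(t = 0, b = 0), fixed_q = c(`in` = 1e-10))
#' solve_network(net)
#' @export
hydraulic_network <- function(edges, fixed_p = numeric(), fixed_q = numeric()) {
  stopifnot(is.data.frame(edges), all(c("from", "to", "R") %in% names(edges)))
  if (any(edges$R <= 0)) stop("every edge resistance must be > 0")
  if (length(fixed_p) < 1L) stop("at least one fixed-pressure node is required")
  nodes <- unique(c(edges$from, edges$to))
  if (!all(names(fixed_p) %in% nodes) || !all(names(fixed_q) %in% nodes)) {
    stop("boundary conditions reference unknown nodes")
  }
  if (length(intersect(names(fixed_p), names(fixed_q)))) {
    stop("a node cannot fix both pressure and flow")
  }
  structure(list(edges = edges, nodes = nodes, fixed_p = fixed_p, fixed_q = fixed_q),
            class = "mf_network")
}

#' Solve a hydraulic network by nodal analysis
#'
#' Assembles the flow-conservation equations at every free node (conductance
#' Laplacian, with injected flows as sources) and solves the resulting linear
#' system. Every edge then satisfies \eqn{\Delta p = R_H Q} and conservation
#' holds at each internal node to solver precision.
#'
#' @param net a \code{\link{hydraulic_network}}.
#' @return list with \code{pressures} (named vector, Pa) and \code{flows}
#'   (data frame \code{from}, \code{to}, \code{R}, \code{Q}; \code{Q} positive
#'   from \code{from} to \code{to}).
#' @export
solve_network <- function(net) {
  stopifnot(inherits(net, "mf_network"))
  nodes <- net$nodes
  free <- setdiff(nodes, names(net$fixed_p))
  p <- stats::setNames(numeric(length(nodes)), nodes)
  p[names(net$fixed_p)] <- net$fixed_p
  if (length(free)) {
    A <- matrix(0, length(free), length(free), dimnames = list(free, free))
    b <- stats::setNames(numeric(length(free)), free)
    b[intersect(free, names(net$fixed_q))] <- net$fixed_q[intersect(free, names(net$fixed_q))]
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      g <- 1 / e$R
      for (nd in c(e$from, e$to)) {
        other <- if (nd == e$from) e$to else e$from
        if (nd %in% free) {
          A[nd, nd] <- A[nd, nd] + g
          if (other %in% free) A[nd, other] <- A[nd, other] - g
          else b[nd] <- b[nd] + g * p[other]
        }
      }
    }
    sol <- tryCatch(solve(A, b), error = function(e) {
      stop("network is ill-posed (singular nodal system); is every node connected to a fixed pressure?")
    })
    p[free] <- sol
  }
  flows <- net$edges
  flows$Q <- (p[flows$from] - p[flows$to]) / flows$R
  list(pressures = p, flows = flows)
}
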