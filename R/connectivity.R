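#' Lateral neighbourhood map of a square lattice
#'
#' Neuron (i, j) is laterally connected to every other neuron (k, l) whose
#' Euclidean lattice distance satisfies `sqrt((i-k)^2 + (j-l)^2) <= radius`.
#' There is no wraparound: boundary neurons simply have fewer neighbours.
#' Neurons are indexed column-major (index `= (col - 1) * shape + row`),
#' matching R's matrix layout.
#'
#' @param shape lattice side length.
#' @param radius neighbourhood radius in lattice units (>= 0).
#' @param include_self keep the neuron itself in its disc (used for
#'   convergent between-nucleus projections; lateral maps exclude it).
#' @return A list with `neighbors` (list of integer neighbour indices per
#'   neuron), `ptr`/`idx` (0-based compressed representation used by the
#'   simulation core) and `counts` (number of neighbours per neuron).
#' @examples
#' # radius 1.6 captures the 8 surrounding neurons of an interior site;
#' # radius 1.4 keeps only the 4 nearest (sqrt(2) > 1.4)
#' cn <- build_connectivity(5, 1.6)
#' cn$counts[13]  # centre neuron of the 5 x 5 grid
#' @export
build_connectivity <- function(shape, radius, include_self = FALSE) {
  if (radius < 0) stop("build_connectivity: radius must be >= 0",
                       call. = FALSE)
  n <- as.integer(shape)
  # offsets within the disc, excluding the neuron itself unless asked
  r2 <- radius^2
  span <- floor(radius)
  off <- expand.grid(dr = -span:span, dc = -span:span)
  off <- off[off$dr^2 + off$dc^2 <= r2 &
               (include_self | !(off$dr == 0 & off$dc == 0)), ,
             drop = FALSE]
  nb <- vector("list", n * n)
  for (col in seq_len(n)) {
    for (row in seq_len(n)) {
      i <- (col - 1L) * n + row
      rr <- row + off$dr
      cc <- col + off$dc
      ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
      nb[[i]] <- as.integer((cc[ok] - 1L) * n + rr[ok])
    }
  }
  counts <- lengths(nb)
  list(neighbors = nb,
       ptr = c(0L, cumsum(counts)),
       idx = as.integer(unlist(nb, use.names = FALSE)) - 1L,
       counts = as.integer(counts))
}
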