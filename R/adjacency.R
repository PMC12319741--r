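#' Channel adjacency from an edge list
#'
#' Builds the symmetric, irreflexive neighbour relation over channel labels
#' used for spatio-temporal clustering.
#'
#' @param edges two-column matrix/data.frame of channel label pairs.
#' @param channels full set of channel labels (order defines the matrix).
#' @return logical channels x channels matrix of class `channel_adjacency`.
#' @export
channel_adjacency <- function(edges, channels) {
  channels <- as.character(channels)
  adj <- matrix(FALSE, length(channels), length(channels),
                dimnames = list(channels, channels))
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    if (!all(edges %in% channels))
      stop_hv("edge list mentions unknown channels: ",
              paste(setdiff(as.vector(edges), channels), collapse = ", "))
    for (i in seq_len(nrow(edges))) {
      a <- match(edges[i, 1], channels); b <- match(edges[i, 2], channels)
      if (a == b) next                        # irreflexive
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  class(adj) <- c("channel_adjacency", "matrix")
  adj
}

#' Chain adjacency over an ordered channel list
#'
#' Convenience montage for fixtures: each channel neighbours its list
#' neighbours.
#' @param channels ordered channel labels.
#' @return a `channel_adjacency` matrix.
#' @export
chain_adjacency <- function(channels) {
  n <- length(channels)
  if (n < 2L) return(channel_adjacency(NULL, channels))
  channel_adjacency(cbind(channels[-n], channels[-1]), channels)
}

#' Adjacency from montage coordinates
#'
#' Connects channels closer than `threshold`; when `threshold` is `NULL` it
#' is chosen as the smallest distance cutoff giving a mean neighbour count in
#' \[4, 8\] (or the closest achievable).
#'
#' @param coords data.frame with columns `label`, `x`, `y` (and optionally
#'   `z`).
#' @param threshold distance cutoff, or `NULL` to choose automatically.
#' @return a `channel_adjacency` matrix.
#' @export
adjacency_from_coords <- function(coords, threshold = NULL) {
  stopifnot(all(c("label", "x", "y") %in% names(coords)))
  xyz <- as.matrix(coords[, intersect(c("x", "y", "z"), names(coords))])
  d <- as.matrix(stats::dist(xyz))
  mean_degree <- function(th) mean(rowSums(d < th & d > 0)) # excl. self
  if (is.null(threshold)) {
    cand <- sort(unique(d[upper.tri(d)]))
    degs <- vapply(cand + 1e-12, mean_degree, numeric(1))
    ok <- which(degs >= 4 & degs <= 8)
    threshold <- if (length(ok)) cand[ok[1]] + 1e-12 else
      cand[which.min(abs(degs - 6))] + 1e-12
  }
  adj <- d < threshold & d > 0
  dimnames(adj) <- list(coords$label, coords$label)
  class(adj) <- c("channel_adjacency", "matrix")
  adj
}

adjacency_neighbours <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ]))
}
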