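# 8-connected component labeling on binary matrices, done sparsely:
# foreground pixels become vertices, 8-neighbour pairs become edges, and
# igraph::components supplies the partition. Shared by hysteresis
# thresholding and contour labeling.

#' @keywords internal
#' @noRd
label_components8 <- function(binary) {
  h <- nrow(binary); w <- ncol(binary)
  idx <- which(binary != 0)
  n <- length(idx)
  if (n == 0L) {
    return(list(labels = integer(0), rows = integer(0), cols = integer(0),
                n_components = 0L))
  }
  r <- ((idx - 1L) %% h) + 1L
  c <- ((idx - 1L) %/% h) + 1L
  lookup <- integer(h * w)
  lookup[idx] <- seq_len(n)
  offs <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (k in 1:4) {
    nr <- r + offs[k, 1]; nc <- c + offs[k, 2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    if (!any(ok)) next
    nb <- lookup[(nc[ok] - 1L) * h + nr[ok]]
    hit <- nb > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  comp <- igraph::components(g)
  list(labels = as.integer(comp$membership), rows = r, cols = c,
       n_components = comp$no)
}
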