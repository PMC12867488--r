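# Independent connected-component oracle: build the voxel adjacency graph
# explicitly and take igraph's components. Deliberately unrelated to the
# package's BFS labelling.
cc_oracle <- function(mask, connectivity) {
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(array(0L, dim = dims))
  node <- array(0L, dim = dims)
  node[idx] <- seq_along(idx)
  co <- arrayInd(idx, dims)
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(offs$dz) + abs(offs$dy) + abs(offs$dx)
  keep <- m > 0 & m <= switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  offs <- offs[keep, ]
  # half-space of offsets so each undirected edge is listed once
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  edges <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(co, 2, as.integer(offs[r, ]), "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    tgt <- node[nb[ok, , drop = FALSE]]
    src <- seq_along(idx)[ok]
    hit <- tgt > 0
    edges <- c(edges, rbind(src[hit], tgt[hit]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  memb <- igraph::components(g)$membership
  lab <- array(0L, dim = dims)
  lab[idx] <- as.integer(memb)
  lab
}

# Canonical form of a labelling: component id becomes the smallest linear
# voxel index it contains, so two labelings agree iff the partitions agree.
canon_labels <- function(lab) {
  idx <- which(lab > 0)
  if (!length(idx)) return(integer(0))
  firsts <- vapply(split(idx, lab[idx]), min, numeric(1))
  out <- unname(firsts[as.character(lab[idx])])
  out[order(idx)]
}
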