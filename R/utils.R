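## Voxel-grid helpers shared across modules.

## Neighbour offsets for a given connectivity (one representative per pair
## is NOT enough for BFS; these are full sets).
.offsets <- function(connectivity = 26L) {
  o <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  o <- o[rowSums(abs(o)) > 0, , drop = FALSE]
  if (connectivity == 6L) o <- o[rowSums(abs(o)) == 1, , drop = FALSE]
  o
}

## Linear index of voxel coordinates (n x 3 matrix), NA outside the grid.
.linIndex <- function(coords, dm) {
  ok <- coords[, 1] >= 1 & coords[, 1] <= dm[1] &
        coords[, 2] >= 1 & coords[, 2] <= dm[2] &
        coords[, 3] >= 1 & coords[, 3] <= dm[3]
  out <- rep(NA_integer_, nrow(coords))
  out[ok] <- coords[ok, 1] + (coords[ok, 2] - 1L) * dm[1] +
    (coords[ok, 3] - 1L) * dm[1] * dm[2]
  out
}

## Physical coordinates (mm) of voxel centers for linear indices.
.voxCoords <- function(idx, dm, dx) {
  (arrayInd(idx, dm) - 0.5) * dx
}

## Edge list between mask voxels under the given connectivity.
.maskEdges <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  idx <- which(mask)
  rank <- integer(prod(dm))
  rank[idx] <- seq_along(idx)
  coords <- arrayInd(idx, dm)
  offs <- .offsets(connectivity)
  offs <- offs[seq_len(nrow(offs) / 2), , drop = FALSE]  # one per pair
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[r, ], "+")
    lin <- .linIndex(nb, dm)
    keep <- !is.na(lin)
    keep[keep] <- mask[lin[keep]]
    if (!any(keep)) next
    from <- c(from, rank[idx[keep]])
    to <- c(to, rank[lin[keep]])
    w <- c(w, rep(sqrt(sum(offs[r, ]^2)), sum(keep)))
  }
  list(from = from, to = to, weight = w, idx = idx, rank = rank)
}

## 26- (or 6-) connected component labelling of a boolean volume.
## Returns an integer array: 0 background, 1..K components (K = attr "n"),
## labelled in decreasing size order.
labelComponents <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  out <- array(0L, dm)
  n <- sum(mask)
  if (n == 0L) { attr(out, "n") <- 0L; return(out) }
  e <- .maskEdges(mask, connectivity)
  g <- igraph::make_graph(rbind(e$from, e$to), n = n, directed = FALSE)
  cmp <- igraph::components(g)
  ord <- order(cmp$csize, decreasing = TRUE)
  relab <- integer(cmp$no); relab[ord] <- seq_len(cmp$no)
  out[e$idx] <- relab[cmp$membership]
  attr(out, "n") <- as.integer(cmp$no)
  out
}

## Binary dilation by a Euclidean ball of radius (mm).
dilateMask <- function(mask, radius_mm, dx) {
  if (radius_mm <= 0 || !any(mask)) return(mask)
  dm <- dim(mask)
  rv <- ceiling(radius_mm / dx)
  off <- as.matrix(expand.grid(-rv:rv, -rv:rv, -rv:rv))
  off <- off[sqrt(rowSums(off^2)) * dx <= radius_mm + 1e-9, , drop = FALSE]
  coords <- arrayInd(which(mask), dm)
  out <- array(FALSE, dm)
  for (r in seq_len(nrow(off))) {
    lin <- .linIndex(sweep(coords, 2, off[r, ], "+"), dm)
    out[lin[!is.na(lin)]] <- TRUE
  }
  out
}

## Multi-source BFS over a mask (26-connectivity): every mask voxel gets the
## value carried by whichever source wave reaches it first. Used for
## transmural label projection and nearest-boundary queries.
.bfsPropagate <- function(mask, sourceIdx, sourceValues) {
  dm <- dim(mask)
  val <- rep(NA_integer_, prod(dm))
  val[sourceIdx] <- sourceValues
  frontier <- sourceIdx
  offs <- .offsets(26L)
  ## within a wave, face neighbours claim voxels before edge/corner ones,
  ## so straight-through columns beat diagonal spread
  offs <- offs[order(rowSums(abs(offs))), , drop = FALSE]
  visited <- array(FALSE, dm)
  visited[sourceIdx] <- TRUE
  while (length(frontier)) {
    coords <- arrayInd(frontier, dm)
    newIdx <- integer(0); newVal <- integer(0)
    for (r in seq_len(nrow(offs))) {
      lin <- .linIndex(sweep(coords, 2, offs[r, ], "+"), dm)
      keep <- !is.na(lin)
      keep[keep] <- mask[lin[keep]] & !visited[lin[keep]]
      if (!any(keep)) next
      cand <- lin[keep]
      dup <- duplicated(cand)
      newIdx <- c(newIdx, cand[!dup])
      newVal <- c(newVal, val[frontier[keep]][!dup])
      visited[cand] <- TRUE
    }
    ## de-duplicate across offsets (first wave wins)
    if (length(newIdx)) {
      dup <- duplicated(newIdx)
      newIdx <- newIdx[!dup]; newVal <- newVal[!dup]
      val[newIdx] <- newVal
    }
    frontier <- newIdx
  }
  val
}

## Geodesic distance (mm) from a voxel set over the wall graph
## (26-connectivity, Euclidean edge weights). Returns a numeric vector over
## the full grid (Inf where unreachable / outside mask).
geodesicDistance <- function(mask, fromIdx, dx) {
  e <- .maskEdges(mask, 26L)
  n <- length(e$idx)
  g <- igraph::make_graph(rbind(e$from, e$to), n = n + 1L, directed = FALSE)
  igraph::E(g)$weight <- e$weight * dx
  src <- e$rank[fromIdx]
  src <- src[src > 0]
  if (!length(src)) stop("no source voxels inside mask")
  g <- igraph::add_edges(g, rbind(rep(n + 1L, length(src)), src),
                         weight = rep(0, length(src)))
  d <- igraph::distances(g, v = n + 1L)[1, seq_len(n)]
  out <- rep(Inf, prod(dim(mask)))
  out[e$idx] <- d
  out
}

## Shortest voxel path (linear indices) between two voxels over the mask.
geodesicPath <- function(mask, fromIdx, toIdx, dx) {
  e <- .maskEdges(mask, 26L)
  g <- igraph::make_graph(rbind(e$from, e$to), n = length(e$idx),
                          directed = FALSE)
  igraph::E(g)$weight <- e$weight * dx
  p <- igraph::shortest_paths(g, from = e$rank[fromIdx],
                              to = e$rank[toIdx])$vpath[[1]]
  e$idx[as.integer(p)]
}

## Surface voxels of a mask: mask voxels with a 6-neighbour outside mask
## (or, when `against` is given, adjacent to an `against` voxel).
surfaceVoxels <- function(mask, against = NULL) {
  dm <- dim(mask)
  idx <- which(mask)
  coords <- arrayInd(idx, dm)
  offs <- .offsets(6L)
  hit <- rep(FALSE, length(idx))
  for (r in seq_len(nrow(offs))) {
    lin <- .linIndex(sweep(coords, 2, offs[r, ], "+"), dm)
    out <- is.na(lin)
    if (is.null(against)) {
      inother <- !out
      inother[!out] <- !mask[lin[!out]]
      hit <- hit | out | inother
    } else {
      inother <- rep(FALSE, length(idx))
      inother[!out] <- against[lin[!out]]
      hit <- hit | inother
    }
  }
  idx[hit]
}

## Endocardial columns of a wall: endo surface voxels plus, for every
## wall voxel, the index (into `endo`) of its first-reaching endocardial
## representative. The label/intensity of a voxel's representative defines
## the transmural (column-constant) value.
.wallColumns <- function(wallMask, bloodPool) {
  endo <- surfaceVoxels(wallMask, against = bloodPool)
  colId <- .bfsPropagate(wallMask, endo, seq_along(endo))
  list(endo = endo, colId = colId)
}

.hashConfig <- function(x) {
  ## stable short fingerprint of a config-like list (no external digest dep)
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}
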