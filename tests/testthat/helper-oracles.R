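# independent oracles and small fixture builders used across test files

# union-find partition over mesh edges applying a patch predicate; the
# independent reference for grow_patches
uf_partition <- function(mesh, values, mode, C = 0, eligible = NULL) {
  m <- nrow(mesh$triangles)
  if (is.null(eligible)) eligible <- rep(TRUE, m)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  accept <- switch(mode,
    tolerance = function(a, b) abs(values[a] - values[b]) < C,
    sign = function(a, b) sign(values[a]) == sign(values[b]),
    binary = function(a, b) values[a] == values[b])
  for (t1 in seq_len(m)) {
    if (!eligible[t1]) next
    for (t2 in mesh$neighbors[[t1]]) {
      if (t2 > t1 && eligible[t2] && accept(t1, t2)) {
        r1 <- find(t1); r2 <- find(t2)
        if (r1 != r2) parent[r1] <- r2
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  split(which(eligible), roots[eligible])
}

# canonical form of a partition: sorted list of sorted member vectors
canon_partition <- function(sets) {
  sets <- lapply(sets, function(s) unname(sort(as.integer(s))))
  unname(sets[order(vapply(sets, `[`, integer(1), 1))])
}

patches_to_partition <- function(patches) {
  canon_partition(lapply(patches, `[[`, "triangle_ids"))
}

# direct trilinear interpolation at a single point, written independently of
# the package's vectorized implementation
trilinear_oracle <- function(grid, p) {
  u <- (p - grid$origin) / grid$spacing
  i0 <- pmin(pmax(floor(u), 0), grid$counts - 2)
  f <- u - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * grid$values[i0[1] + 1 + dx, i0[2] + 1 + dy, i0[3] + 1 + dz]
  }
  acc
}

# exhaustive first-split oracle for the ADtree Z criterion (root precondition
# only, uniform weights after the root update)
brute_force_first_split <- function(X, y) {
  y <- ifelse(y > 0, 1, -1)
  n <- nrow(X)
  w <- rep(1 / n, n)
  root <- 0.5 * log(sum(w[y > 0]) / sum(w[y < 0]))
  w <- w * exp(-y * root)
  w <- w / sum(w)
  best <- NULL
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[, f]))
    if (length(xs) < 2) next
    for (thr in (xs[-1] + xs[-length(xs)]) / 2) {
      le <- X[, f] <= thr
      Z <- 2 * (sqrt(sum(w[le & y > 0]) * sum(w[le & y < 0])) +
                sqrt(sum(w[!le & y > 0]) * sum(w[!le & y < 0])))
      if (is.null(best) || Z < best$Z ||
          (Z == best$Z && (f < best$f || (f == best$f && thr < best$thr))))
        best <- list(Z = Z, f = f, thr = thr)
    }
  }
  best
}

# AUC as concordant-pair count (ties half), the Mann-Whitney reference
pair_count_auc <- function(labels, scores) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# minimal ProteinStructure from an atom table
toy_structure <- function(atoms, sequence = c(A = "A")) {
  structure(list(atoms = atoms, sequence = sequence),
            class = "ProteinStructure")
}

one_atom_structure <- function(element = "C", residue = "ALA", name = "CA") {
  toy_structure(data.frame(
    serial = 1L, name = name, residue_name = residue, chain = "A",
    residue_seq = 1L, x = 0, y = 0, z = 0, element = element,
    stringsAsFactors = FALSE))
}

# connected components of a mesh (triangle adjacency), for Euler checks
mesh_components <- function(mesh) {
  m <- nrow(mesh$triangles)
  comp <- integer(m)
  cur <- 0L
  for (s in seq_len(m)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      t1 <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (t2 in mesh$neighbors[[t1]]) if (comp[t2] == 0) {
        comp[t2] <- cur
        stack <- c(stack, t2)
      }
    }
  }
  comp
}

euler_characteristic <- function(mesh, tri_ids) {
  tris <- mesh$triangles[tri_ids, , drop = FALSE]
  V <- length(unique(as.vector(tris)))
  ed <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  E <- length(unique(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))))
  V - E + nrow(tris)
}

# a random small mesh fixture: icosphere with a random channel
random_channel_mesh <- function(seed, subdivisions = 2,
                               values = c(-1, 0, 1)) {
  mesh <- icosphere(subdivisions)
  set.seed(seed)
  mesh$channels$v <- sample(values, nrow(mesh$triangles), replace = TRUE)
  mesh
}

# one PDB-format ATOM line with correct fixed columns
pdb_line <- function(serial, name, res, chain, seq, x, y, z, element,
                     record = "ATOM  ", altloc = " ", occ = 1.0) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, res, chain, seq, x, y, z, occ, 0,
          element)
}
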