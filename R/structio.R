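# structio: structure / grid input, surface construction, property mapping

#' Read a protein structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records of the first MODEL. Alternate
#' locations are resolved to the highest-occupancy copy and water molecules
#' (HOH/WAT/DOD) are excluded.
#'
#' @param path Path to a PDB-format file.
#' @return A \code{ProteinStructure}: list with \code{atoms} (data.frame with
#'   columns serial, name, residue_name, chain, residue_seq, x, y, z, element)
#'   and \code{sequence} (named character vector, one-letter string per chain).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  # restrict to first model if MODEL records present
  model_at <- which(trimws(rec) == "MODEL")
  if (length(model_at) > 1) {
    endm <- which(trimws(rec) == "ENDMDL")
    stop_at <- if (length(endm)) endm[1] else model_at[2]
    lines <- lines[seq_len(stop_at - 1)]
    rec <- rec[seq_len(stop_at - 1)]
  }
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM records in ", path)

  fld <- function(a, b) trimws(substr(lines, a, b))
  water <- fld(18, 20) %in% c("HOH", "WAT", "DOD")
  lines <- lines[!water]
  if (!length(lines)) stop("no non-water atoms in ", path)

  atoms <- data.frame(
    serial = as.integer(fld(7, 11)),
    name = fld(13, 16),
    altloc = substr(lines, 17, 17),
    residue_name = fld(18, 20),
    chain = substr(lines, 22, 22),
    residue_seq = as.integer(fld(23, 26)),
    x = as.numeric(fld(31, 38)),
    y = as.numeric(fld(39, 46)),
    z = as.numeric(fld(47, 54)),
    occupancy = suppressWarnings(as.numeric(fld(55, 60))),
    element = fld(77, 78),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("malformed coordinates in ", path)
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  no_el <- atoms$element == ""
  if (any(no_el)) # infer element from atom name (first alphabetic character)
    atoms$element[no_el] <- substr(gsub("[^A-Za-z].*", "",
                                        gsub("^[0-9]+", "", atoms$name[no_el])), 1, 1)
  atoms$element <- toupper(atoms$element)

  # altLoc: keep highest occupancy copy per (chain, residue, atom name)
  if (any(atoms$altloc != " ")) {
    key <- paste(atoms$chain, atoms$residue_seq, atoms$name)
    ord <- order(key, -atoms$occupancy)
    atoms <- atoms[ord, ][!duplicated(key[ord]), ]
    atoms <- atoms[order(atoms$serial), ]
  }
  atoms$altloc <- NULL
  atoms$occupancy <- NULL
  rownames(atoms) <- NULL

  res_key <- paste(atoms$chain, atoms$residue_seq)
  first <- !duplicated(res_key)
  seqs <- tapply(aa_three_to_one(atoms$residue_name[first]),
                 atoms$chain[first],
                 function(s) paste(s, collapse = ""))
  structure(list(atoms = atoms, sequence = unlist(as.list(seqs))),
            class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  cat("ProteinStructure:", nrow(x$atoms), "atoms,",
      length(x$sequence), "chain(s), sequence:",
      paste(x$sequence, collapse = "/"), "\n")
  invisible(x)
}

# --- scalar grids (OpenDX) --------------------------------------------------

#' Construct a regular scalar grid
#'
#' @param origin,spacing Numeric length-3 (Angstrom; spacing per cell).
#' @param values 3D array indexed \code{[x, y, z]}.
#' @return A \code{ScalarGrid}.
#' @export
scalar_grid <- function(origin, spacing, values) {
  stopifnot(length(origin) == 3, length(spacing) == 3, all(spacing > 0),
            length(dim(values)) == 3, all(is.finite(values)))
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 counts = dim(values), values = values),
            class = "ScalarGrid")
}

#' @export
print.ScalarGrid <- function(x, ...) {
  cat("ScalarGrid:", paste(x$counts, collapse = " x "),
      "origin", paste(signif(x$origin, 4), collapse = " "),
      "spacing", paste(signif(x$spacing, 4), collapse = " "), "\n")
  invisible(x)
}

#' Read an OpenDX scalar grid
#'
#' Supports the APBS dialect (\code{object 1 class gridpositions counts},
#' axis-aligned \code{delta} rows, values in z-fastest order).
#'
#' @param path Path to a .dx file.
#' @return A \code{ScalarGrid} with values remapped to x,y,z array order.
#' @export
read_dx <- function(path) {
  if (!file.exists(path)) stop("cannot read DX file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("gridpositions", lines, value = TRUE)
  if (!length(gp)) stop("not an OpenDX gridpositions file: ", path)
  counts <- as.integer(tail(strsplit(trimws(gp[1]), "\\s+")[[1]], 3))
  if (length(counts) != 3 || anyNA(counts) || any(counts < 1))
    stop("bad counts in DX header")
  org_line <- grep("^\\s*origin", lines, value = TRUE)
  if (!length(org_line)) stop("missing origin in DX header")
  origin <- as.numeric(strsplit(trimws(org_line[1]), "\\s+")[[1]][2:4])
  delta_lines <- grep("^\\s*delta", lines, value = TRUE)
  if (length(delta_lines) != 3) stop("unsupported grid: need 3 delta rows")
  delta <- t(vapply(delta_lines, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]), numeric(3)))
  if (any(abs(delta[upper.tri(delta) | lower.tri(delta)]) > 1e-12))
    stop("unsupported grid: sheared (non-diagonal) delta")
  spacing <- diag(delta)
  if (any(spacing <= 0)) stop("unsupported grid: non-positive delta")

  data_at <- grep("data follows", lines)
  if (!length(data_at)) stop("missing data section in DX file")
  body <- lines[(data_at[1] + 1):length(lines)]
  body <- body[!grepl("^\\s*(object|attribute|component|end)", body)]
  vals <- as.numeric(unlist(strsplit(trimws(body[nzchar(trimws(body))]), "\\s+")))
  n <- prod(counts)
  if (length(vals) < n) stop("DX data truncated: expected ", n, " values")
  vals <- vals[seq_len(n)]
  # file order is z-fastest, x-slowest; R arrays are x-fastest
  arr <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  scalar_grid(origin, spacing, arr)
}

#' Write a ScalarGrid as OpenDX
#' @param grid A \code{ScalarGrid}.
#' @param path Output path.
#' @export
write_dx <- function(grid, path) {
  stopifnot(inherits(grid, "ScalarGrid"))
  n <- prod(grid$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by mtdminer",
    sprintf("object 1 class gridpositions counts %d %d %d",
            grid$counts[1], grid$counts[2], grid$counts[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing[1]),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing[2]),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d",
            grid$counts[1], grid$counts[2], grid$counts[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))  # z-fastest on disk
  full <- seq_len(n %/% 3 * 3)
  if (length(full))
    writeLines(apply(matrix(sprintf("%.9e", vals[full]), nrow = 3), 2,
                     paste, collapse = " "), con)
  if (n %% 3)
    writeLines(paste(sprintf("%.9e", vals[(n %/% 3 * 3 + 1):n]), collapse = " "), con)
  invisible(path)
}

# --- surface meshes ---------------------------------------------------------

triangle_geometry <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2,
       normal = cr / ifelse(nrm > 0, nrm, 1),
       centroid = (a + b + c_) / 3)
}

mesh_adjacency <- function(triangles) {
  m <- nrow(triangles)
  ev <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  key <- paste(pmin(ev[, 1], ev[, 2]), pmax(ev[, 1], ev[, 2]))
  tri_of_edge <- rep(seq_len(m), 3)
  sp <- split(tri_of_edge, key)
  neigh <- vector("list", m)
  for (tris in sp) {
    if (length(tris) == 2) {
      neigh[[tris[1]]] <- c(neigh[[tris[1]]], tris[2])
      neigh[[tris[2]]] <- c(neigh[[tris[2]]], tris[1])
    }
  }
  lapply(neigh, function(v) if (is.null(v)) integer(0) else sort(unique(v)))
}

#' Construct a SurfaceMesh
#'
#' A triangulated closed surface with per-triangle area, outward unit normal,
#' centroid, edge adjacency, optional source-atom/residue attribution and
#' named per-triangle scalar value channels.
#'
#' @param vertices n x 3 numeric matrix (Angstrom).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param triangle_atom Optional integer vector: source atom row per triangle.
#' @param triangle_residue Optional character vector: source residue (3-letter
#'   code) per triangle.
#' @param channels Named list of per-triangle numeric vectors.
#' @param drop_degenerate Drop zero-area triangles (default TRUE).
#' @return A \code{SurfaceMesh}.
#' @export
surface_mesh <- function(vertices, triangles, triangle_atom = NULL,
                         triangle_residue = NULL, channels = list(),
                         drop_degenerate = TRUE) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3, all(triangles >= 1),
            all(triangles <= nrow(vertices)))
  if (any(triangles[, 1] == triangles[, 2] | triangles[, 1] == triangles[, 3] |
          triangles[, 2] == triangles[, 3]))
    stop("triangle with repeated vertex index")
  geo <- triangle_geometry(vertices, triangles)
  if (drop_degenerate && any(geo$area <= 1e-12)) {
    keep <- geo$area > 1e-12
    triangles <- triangles[keep, , drop = FALSE]
    if (!is.null(triangle_atom)) triangle_atom <- triangle_atom[keep]
    if (!is.null(triangle_residue)) triangle_residue <- triangle_residue[keep]
    channels <- lapply(channels, function(ch) ch[keep])
    geo <- triangle_geometry(vertices, triangles)
  }
  structure(list(
    vertices = vertices, triangles = triangles,
    triangle_area = geo$area, triangle_normal = geo$normal,
    triangle_centroid = geo$centroid,
    triangle_atom = triangle_atom, triangle_residue = triangle_residue,
    channels = channels,
    neighbors = mesh_adjacency(triangles)
  ), class = "SurfaceMesh")
}

#' @export
print.SurfaceMesh <- function(x, ...) {
  cat("SurfaceMesh:", nrow(x$vertices), "vertices,", nrow(x$triangles),
      "triangles, total area", sprintf("%.2f", sum(x$triangle_area)), "A^2\n")
  if (length(x$channels))
    cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Build a solvent-exposed surface mesh from a structure
#'
#' Extracts the zero level set of the probe-inflated signed distance field
#' min_i(|p - c_i| - r_i) - probe over the atoms (marching tetrahedra on a
#' regular grid), so a lone atom yields a sphere-like mesh of radius
#' r_vdW + probe. Each triangle is attributed to the nearest atom center and
#' inherits that atom's residue.
#'
#' @param struct A \code{ProteinStructure}.
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4).
#' @param grid_spacing Marching grid spacing in Angstrom (default 0.6);
#'   smaller values give denser, more accurate meshes.
#' @return A \code{SurfaceMesh} with atom and residue attribution.
#' @export
build_surface <- function(struct, probe_radius = 1.4, grid_spacing = 0.6) {
  stopifnot(inherits(struct, "ProteinStructure"))
  at <- struct$atoms
  if (!nrow(at)) stop("empty structure")
  centers <- cbind(at$x, at$y, at$z)
  if (nrow(at) > 1 && max(dist(centers)) < 1e-6)
    stop("degenerate geometry: all atoms coincident")
  radii <- ELEMENT_RADII[at$element]
  radii[is.na(radii)] <- 1.7
  pad <- max(radii) + probe_radius + 2 * grid_spacing
  lo <- apply(centers, 2, min) - pad
  hi <- apply(centers, 2, max) + pad
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / grid_spacing)) + 1L)
  field <- .sphere_field(counts, lo, rep(grid_spacing, 3), centers,
                         unname(radii), probe_radius)
  mt <- .march_tetra(field, counts, lo, rep(grid_spacing, 3))
  if (!nrow(mt$triangles)) stop("degenerate geometry: no surface extracted")
  geo <- triangle_geometry(mt$vertices, mt$triangles)
  # nearest atom center per triangle centroid
  near <- nearest_point_index(geo$centroid, centers)
  surface_mesh(mt$vertices, mt$triangles,
               triangle_atom = near,
               triangle_residue = at$residue_name[near])
}

nearest_point_index <- function(query, ref) {
  best_d <- rep(Inf, nrow(query))
  best_i <- rep(1L, nrow(query))
  for (i in seq_len(nrow(ref))) {
    d <- (query[, 1] - ref[i, 1])^2 + (query[, 2] - ref[i, 2])^2 +
      (query[, 3] - ref[i, 3])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_i[upd] <- i
  }
  best_i
}

# trilinear interpolation of grid values at points (n x 3); out-of-bounds
# points are clamped to the nearest in-bounds corner
trilinear <- function(grid, pts) {
  cnt <- grid$counts
  u <- sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/")
  oob <- u[, 1] < 0 | u[, 1] > cnt[1] - 1 |
         u[, 2] < 0 | u[, 2] > cnt[2] - 1 |
         u[, 3] < 0 | u[, 3] > cnt[3] - 1
  u[, 1] <- pmin(pmax(u[, 1], 0), cnt[1] - 1)
  u[, 2] <- pmin(pmax(u[, 2], 0), cnt[2] - 1)
  u[, 3] <- pmin(pmax(u[, 3], 0), cnt[3] - 1)
  i0 <- pmin(floor(u), rep(cnt - 2, each = nrow(u)))
  i0 <- matrix(pmax(i0, 0), ncol = 3)
  fr <- u - i0
  v <- grid$values
  idx <- function(dx, dy, dz)
    v[cbind(i0[, 1] + 1 + dx, i0[, 2] + 1 + dy, i0[, 3] + 1 + dz)]
  val <-
    idx(0, 0, 0) * (1 - fr[, 1]) * (1 - fr[, 2]) * (1 - fr[, 3]) +
    idx(1, 0, 0) * fr[, 1] * (1 - fr[, 2]) * (1 - fr[, 3]) +
    idx(0, 1, 0) * (1 - fr[, 1]) * fr[, 2] * (1 - fr[, 3]) +
    idx(1, 1, 0) * fr[, 1] * fr[, 2] * (1 - fr[, 3]) +
    idx(0, 0, 1) * (1 - fr[, 1]) * (1 - fr[, 2]) * fr[, 3] +
    idx(1, 0, 1) * fr[, 1] * (1 - fr[, 2]) * fr[, 3] +
    idx(0, 1, 1) * (1 - fr[, 1]) * fr[, 2] * fr[, 3] +
    idx(1, 1, 1) * fr[, 1] * fr[, 2] * fr[, 3]
  list(values = val, oob = oob)
}

#' Map a scalar grid onto a surface channel
#'
#' Each triangle is assigned the trilinear (8-corner weighted) average of the
#' grid at the probe point one \code{offset} along the outward normal from the
#' triangle centroid. Out-of-bounds probe points receive the nearest in-bounds
#' value and are counted in a warning.
#'
#' @param mesh A \code{SurfaceMesh}.
#' @param grid A \code{ScalarGrid} (e.g. electrostatic potential in kT/e).
#' @param offset Distance along the normal, Angstrom (default 1.0).
#' @param channel_name Name under which the channel is stored.
#' @return The mesh with the new channel added; geometry untouched.
#' @export
map_grid_to_surface <- function(mesh, grid, offset = 1.0,
                                channel_name = "elec") {
  stopifnot(inherits(mesh, "SurfaceMesh"), inherits(grid, "ScalarGrid"))
  probe <- mesh$triangle_centroid + offset * mesh$triangle_normal
  tl <- trilinear(grid, probe)
  if (all(tl$oob)) stop("mapping error: grid and mesh are disjoint in space")
  if (any(tl$oob))
    warning(sum(tl$oob), " probe point(s) outside the grid; clamped")
  mesh$channels[[channel_name]] <- tl$values
  mesh
}

#' Map Kyte-Doolittle hydrophobicity onto a surface channel
#'
#' Each triangle takes the hydropathy value of the residue that gave rise to
#' it. Non-standard residues get 0 with a warning.
#'
#' @inheritParams map_grid_to_surface
#' @param struct The source \code{ProteinStructure} (unused beyond validation;
#'   attribution is carried by the mesh).
#' @export
map_hydrophobicity <- function(mesh, struct = NULL, channel_name = "hyd") {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  if (is.null(mesh$triangle_residue)) stop("mesh lacks residue attribution")
  val <- unname(KD_SCALE[mesh$triangle_residue])
  if (anyNA(val)) {
    warning(sum(is.na(val)), " triangle(s) from non-standard residues; value 0")
    val[is.na(val)] <- 0
  }
  mesh$channels[[channel_name]] <- val
  mesh
}

#' Map hydrogen-bonding capability onto a surface channel
#'
#' A triangle's value is 1 when its source atom can donate or accept a
#' hydrogen bond (backbone N/O, or a side-chain N/O/S atom of
#' S,T,Y,N,Q,D,E,K,R,H,W,C,M per a fixed table), else 0.
#'
#' @inheritParams map_hydrophobicity
#' @export
map_hbond <- function(mesh, struct, channel_name = "hbond") {
  stopifnot(inherits(mesh, "SurfaceMesh"), inherits(struct, "ProteinStructure"))
  if (is.null(mesh$triangle_atom)) stop("mesh lacks atom attribution")
  at <- struct$atoms[mesh$triangle_atom, ]
  backbone <- at$name %in% c("N", "O", "OXT")
  side <- mapply(function(res, nm) {
    tbl <- HBOND_SIDECHAIN[[res]]
    !is.null(tbl) && nm %in% tbl
  }, at$residue_name, at$name, USE.NAMES = FALSE)
  mesh$channels[[channel_name]] <- as.numeric(backbone | side)
  mesh
}

#' Screened-Coulomb electrostatic grid (fallback when no PB solver output)
#'
#' Computes sum_i q_i exp(-d_i / lambda) / (4 pi eps d_i) on a regular grid,
#' with d_i clamped below at 1 Angstrom. Charges come from a deliberately
#' coarse table (integer side-chain charges on terminal atoms; see
#' \code{CHARGE_TABLE}); ingesting a Poisson-Boltzmann DX grid via
#' \code{\link{read_dx}} is the fidelity path.
#'
#' @param struct A \code{ProteinStructure}.
#' @param spacing Grid spacing, Angstrom.
#' @param padding Margin beyond the atom bounding box, Angstrom.
#' @param ionic_screening_length Debye screening length lambda, Angstrom;
#'   \code{Inf} disables screening. Default 8 (approx. 150 mM ionic strength).
#' @param dielectric Relative dielectric constant (default 80).
#' @return A \code{ScalarGrid}.
#' @export
coulomb_grid <- function(struct, spacing = 1.0, padding = 8.0,
                         ionic_screening_length = 8.0, dielectric = 80) {
  stopifnot(inherits(struct, "ProteinStructure"))
  at <- struct$atoms
  if (!nrow(at)) stop("empty structure")
  charges <- atom_charges(at)
  lo <- c(min(at$x), min(at$y), min(at$z)) - padding
  hi <- c(max(at$x), max(at$y), max(at$z)) + padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + spacing * (seq_len(counts[1]) - 1)
  gy <- lo[2] + spacing * (seq_len(counts[2]) - 1)
  gz <- lo[3] + spacing * (seq_len(counts[3]) - 1)
  vals <- array(0, dim = counts)
  hot <- which(charges != 0)
  if (length(hot)) {
    px <- array(gx, dim = counts)
    py <- array(rep(gy, each = counts[1]), dim = counts)
    pz <- array(rep(gz, each = counts[1] * counts[2]), dim = counts)
    for (i in hot) {
      d <- sqrt((px - at$x[i])^2 + (py - at$y[i])^2 + (pz - at$z[i])^2)
      d <- pmax(d, 1)
      scr <- if (is.finite(ionic_screening_length))
        exp(-d / ionic_screening_length) else 1
      vals <- vals + charges[i] * scr / (4 * pi * dielectric * d)
    }
  }
  scalar_grid(lo, rep(spacing, 3), vals)
}

# per-atom partial charges from the coarse built-in table
atom_charges <- function(atoms) {
  q <- numeric(nrow(atoms))
  res_key <- paste(atoms$chain, atoms$residue_seq)
  for (rk in unique(res_key)) {
    rows <- which(res_key == rk)
    entry <- CHARGE_TABLE[[atoms$residue_name[rows[1]]]]
    if (is.null(entry)) next
    term <- rows[atoms$name[rows] %in% entry$atoms]
    if (!length(term)) term <- rows[atoms$name[rows] == "CB"]
    if (!length(term)) term <- rows[atoms$name[rows] == "CA"]
    if (!length(term)) term <- rows[1]
    q[term] <- entry$q / length(term)
  }
  q
}

# --- OFF mesh I/O -----------------------------------------------------------

#' Write a SurfaceMesh in OFF format
#' @param mesh A \code{SurfaceMesh}.
#' @param path Output path.
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "SurfaceMesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$triangles)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Read an OFF mesh
#' @param path Path to an OFF file.
#' @return A \code{SurfaceMesh} (no attribution or channels).
#' @export
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (toupper(lines[1]) != "OFF") stop("not an OFF file: ", path)
  hdr <- as.integer(strsplit(lines[2], "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  verts <- matrix(as.numeric(unlist(strsplit(lines[3:(2 + nv)], "\\s+"))),
                  ncol = 3, byrow = TRUE)
  face_rows <- strsplit(lines[(3 + nv):(2 + nv + nf)], "\\s+")
  faces <- t(vapply(face_rows, function(r) as.integer(r[2:4]), integer(3))) + 1L
  surface_mesh(verts, faces)
}
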