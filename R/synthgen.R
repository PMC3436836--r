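# synthgen: synthetic fixtures with analytic ground truth

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron with vertices projected to the sphere of the given
#' radius; triangles are consistently outward-oriented.
#'
#' @param subdivisions Number of 4-way subdivisions (0 = icosahedron;
#'   4 gives 5120 triangles).
#' @param radius Sphere radius.
#' @return A \code{SurfaceMesh}.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  norm_rows <- function(m) m / sqrt(rowSums(m^2))
  v <- norm_rows(v)
  for (s in seq_len(subdivisions)) {
    env <- new.env()
    nv <- nrow(v)
    verts <- vector("list", 0)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      got <- env[[key]]
      if (!is.null(got)) return(got)
      p <- (v[a, ] + v[b, ])
      p <- p / sqrt(sum(p^2))
      verts[[length(verts) + 1]] <<- p
      id <- nv + length(verts)
      env[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c_, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, verts))
    f <- nf
  }
  surface_mesh(v * radius, f)
}

#' Sphere mesh with planted same-value caps of known area
#'
#' Builds an icosphere and plants spherical caps in a value channel: every
#' triangle whose centroid direction lies within a cap's angular radius gets
#' the cap value, the rest the background value. The closed-form cap areas
#' 2 pi R^2 (1 - cos theta) are returned for downstream assertions.
#'
#' @param subdivisions,radius Passed to \code{\link{icosphere}}.
#' @param caps List of caps, each \code{list(center = 3-vector, theta =
#'   angular radius in radians, value = planted value)}. Caps must not
#'   overlap (pairwise center separation > sum of radii).
#' @param background Background channel value (default 0).
#' @param channel Channel name (default "planted").
#' @return List with \code{mesh} (channel populated), \code{cap_areas}
#'   (closed form, per cap) and \code{cap_triangles} (indices per cap).
#' @export
make_sphere_mesh <- function(subdivisions = 4, radius = 1, caps = list(),
                             background = 0, channel = "planted") {
  if (length(caps) > 1) {
    ctr <- t(vapply(caps, function(cp) cp$center / sqrt(sum(cp$center^2)),
                    numeric(3)))
    for (i in seq_len(length(caps) - 1))
      for (j in (i + 1):length(caps)) {
        sep <- acos(pmin(1, pmax(-1, sum(ctr[i, ] * ctr[j, ]))))
        if (sep <= caps[[i]]$theta + caps[[j]]$theta)
          stop("overlapping caps")
      }
  }
  mesh <- icosphere(subdivisions, radius)
  val <- rep(background, nrow(mesh$triangles))
  dirs <- mesh$triangle_centroid /
    sqrt(rowSums(mesh$triangle_centroid^2))
  cap_tri <- vector("list", length(caps))
  for (i in seq_along(caps)) {
    cp <- caps[[i]]
    u <- cp$center / sqrt(sum(cp$center^2))
    ang <- acos(pmin(1, pmax(-1, dirs %*% u)))
    cap_tri[[i]] <- which(ang < cp$theta)
    val[cap_tri[[i]]] <- cp$value
  }
  mesh$channels[[channel]] <- val
  list(mesh = mesh,
       cap_areas = vapply(caps, function(cp)
         2 * pi * radius^2 * (1 - cos(cp$theta)), numeric(1)),
       cap_triangles = cap_tri)
}

#' Synthetic labeled alignment with planted class-specific windows
#'
#' Rows are sampled i.i.d. per column: background columns share one residue
#' distribution across classes; inside each planted window the two classes
#' use their own distributions, creating known discriminative positions.
#'
#' @param L Alignment length.
#' @param windows List of \code{list(start, length, plus, minus)} where
#'   \code{plus}/\code{minus} are named probability vectors over one-letter
#'   residue codes (must sum to 1). Windows must be disjoint and inside L.
#' @param background Named probability vector for non-window columns
#'   (default: uniform over the 20 residues).
#' @param n_plus,n_minus Rows per class.
#' @param seed RNG seed.
#' @return A \code{\link{labeled_alignment}} with attribute
#'   \code{"windows"}.
#' @export
make_labeled_alignment <- function(L = 40, windows = list(),
                                   background = NULL,
                                   n_plus = 30, n_minus = 30, seed = 1) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), unname(AA1[AA3]))
  stopifnot(abs(sum(background) - 1) < 1e-9)
  cols_of <- function(w) w$start:(w$start + w$length - 1)
  used <- unlist(lapply(windows, cols_of))
  if (anyDuplicated(used) || any(used < 1) || any(used > L))
    stop("windows must be disjoint and within L")
  for (w in windows)
    stopifnot(abs(sum(w$plus) - 1) < 1e-9, abs(sum(w$minus) - 1) < 1e-9)

  n <- n_plus + n_minus
  labels <- c(rep(1L, n_plus), rep(0L, n_minus))
  with_seed(seed, {
    cm <- matrix("", n, L)
    for (j in seq_len(L)) {
      w <- NULL
      for (wi in windows) if (j %in% cols_of(wi)) { w <- wi; break }
      if (is.null(w)) {
        cm[, j] <- sample(names(background), n, replace = TRUE,
                          prob = background)
      } else {
        cm[labels == 1, j] <- sample(names(w$plus), n_plus, replace = TRUE,
                                     prob = w$plus)
        cm[labels == 0, j] <- sample(names(w$minus), n_minus, replace = TRUE,
                                     prob = w$minus)
      }
    }
    aln <- labeled_alignment(sprintf("seq%03d", seq_len(n)),
                             apply(cm, 1, paste, collapse = ""), labels)
    attr(aln, "windows") <- windows
    aln
  })
}

#' Planted-motif alignment (convenience wrapper)
#'
#' One discriminative window: in the + class each motif column shows a fixed
#' preferred residue with probability \code{strength} (rest uniform); the -
#' class is uniform. \code{strength = 0.8} gives per-column log-odds of about
#' ln(0.8/0.05) ~ 2.8, well above 1.
#'
#' @param L,n_plus,n_minus,seed As in \code{\link{make_labeled_alignment}}.
#' @param start,length Window placement (default columns 10..13).
#' @param strength Probability of the preferred residue in the + class.
#' @return A \code{\link{labeled_alignment}}.
#' @export
planted_motif_alignment <- function(L = 40, start = 10, length = 4,
                                    strength = 0.8, n_plus = 30,
                                    n_minus = 30, seed = 1) {
  aas <- unname(AA1[AA3])
  unif <- stats::setNames(rep(1 / 20, 20), aas)
  preferred <- rep_len(c("K", "R", "W", "F", "D", "E"), length)
  plus <- stats::setNames(rep((1 - strength) / 19, 20), aas)
  # per-column preference is encoded by rotating the same high-mass vector;
  # make_labeled_alignment draws the whole window from one distribution per
  # class, so use separate single-column windows
  windows <- lapply(seq_len(length), function(i) {
    p <- stats::setNames(rep((1 - strength) / 19, 20), aas)
    p[preferred[i]] <- strength
    list(start = start + i - 1, length = 1, plus = p, minus = unif)
  })
  aln <- make_labeled_alignment(L, windows, n_plus = n_plus,
                                n_minus = n_minus, seed = seed)
  attr(aln, "motif") <- list(start = start, length = length)
  aln
}

#' Synthetic tabular dataset generated by known threshold rules
#'
#' X is uniform on [0,1]^d; each generating rule votes +1 or -1 according to
#' a threshold test on one feature and the clean label is the sign of the
#' summed votes (an odd rule count avoids ties). Labels are then flipped with
#' the given noise rate, so the Bayes accuracy is 1 - noise.
#'
#' @param n,d Instances and features (defaults 300 x 60, emulating the
#'   35 + 25 joined feature space).
#' @param n_rules Number of generating rules (default 3, odd).
#' @param noise Label-flip rate in [0, 0.5).
#' @param seed RNG seed.
#' @return List with \code{X}, \code{y} (0/1), \code{rules} (feature,
#'   threshold, vote per rule) and \code{bayes_accuracy}.
#' @export
make_rule_dataset <- function(n = 300, d = 60, n_rules = 3, noise = 0.1,
                              seed = 1) {
  stopifnot(noise >= 0, noise < 0.5)
  with_seed(seed, {
    X <- matrix(runif(n * d), n, d)
    feats <- sample.int(d, n_rules)
    thr <- runif(n_rules, 0.25, 0.75)
    vote <- sample(c(-1, 1), n_rules, replace = TRUE)
    votes <- sapply(seq_len(n_rules), function(j)
      vote[j] * ifelse(X[, feats[j]] > thr[j], 1, -1))
    if (n_rules == 1) votes <- matrix(votes, ncol = 1)
    clean <- as.integer(rowSums(votes) > 0)
    flip <- runif(n) < noise
    y <- ifelse(flip, 1L - clean, clean)
    list(X = X, y = y,
         rules = data.frame(feature = feats, threshold = thr, vote = vote),
         bayes_accuracy = 1 - noise)
  })
}

#' Toy extended-chain protein structure
#'
#' Places each residue of the given composition along an extended chain with
#' backbone N, CA, C, O atoms and a CB pseudo side-chain atom (omitted for
#' glycine), with a small seeded coordinate jitter. Valid PDB text is
#' produced by \code{\link{write_pdb}} and round-trips through
#' \code{\link{read_pdb}}.
#'
#' @param n_residues Number of residues.
#' @param composition One-letter codes, recycled to n_residues (default "A").
#' @param seed RNG seed for the jitter.
#' @param jitter Coordinate jitter SD in Angstrom (default 0.05).
#' @return A \code{ProteinStructure}.
#' @export
make_toy_structure <- function(n_residues, composition = "A", seed = 1,
                               jitter = 0.05) {
  stopifnot(n_residues >= 1)
  letters1 <- rep_len(strsplit(paste(composition, collapse = ""), "")[[1]],
                      n_residues)
  three <- names(AA1)[match(letters1, AA1)]
  if (anyNA(three)) stop("unknown residue code in composition")
  rows <- list()
  serial <- 0L
  with_seed(seed, {
    for (i in seq_len(n_residues)) {
      ca <- c(3.8 * (i - 1), 0.3 * (i %% 2), 0)
      atoms <- list(
        N = ca + c(-1.2, 0.8, 0.1), CA = ca, C = ca + c(1.2, 0.8, -0.1),
        O = ca + c(1.4, 1.9, -0.3))
      if (three[i] != "GLY") atoms$CB <- ca + c(0, -1.5, 0.2)
      for (nm in names(atoms)) {
        serial <- serial + 1L
        p <- atoms[[nm]] + rnorm(3, sd = jitter)
        rows[[serial]] <- data.frame(
          serial = serial, name = nm, residue_name = three[i], chain = "A",
          residue_seq = i, x = p[1], y = p[2], z = p[3],
          element = substr(nm, 1, 1), stringsAsFactors = FALSE)
      }
    }
  })
  atoms <- do.call(rbind, rows)
  structure(list(atoms = atoms,
                 sequence = c(A = paste(letters1, collapse = ""))),
            class = "ProteinStructure")
}

#' Write a ProteinStructure as PDB text
#' @param struct A \code{ProteinStructure}.
#' @param path Output path.
#' @export
write_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "ProteinStructure"))
  at <- struct$atoms
  name4 <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                  at$name)
  lines <- sprintf(
    "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$serial, name4, at$residue_name, at$chain, at$residue_seq,
    at$x, at$y, at$z, 1.0, 0.0, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
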