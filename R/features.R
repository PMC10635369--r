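# Structurally derived features (SDF) and the raw-coordinate baseline (CF).
#
# Per residue pair, five geometric quantities are computed: the inter-helical
# tilt angle theta between the axes of the two host helices; the mean (D1) and
# population standard deviation (SD) of all heavy-atom cross distances; the
# C-alpha distance (D-alpha); and the relative residue angle delta between the
# residue-plane normals. The 3x3 sequence window around the pair (excluding
# the center) yields 8 neighbor pairs, concatenated to a length-40 SDF vector
# or, for the baseline, 8 x 24 raw N/CA/O/CB coordinates (length 192).

# fixed row-major window order over (di, dj), center excluded
WINDOW_OFFSETS <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                        c(0, 1), c(1, -1), c(1, 0), c(1, 1))

#' Estimate the axis of one TM helix
#'
#' The axis orientation is the normalized mean over i of the unit vector from
#' O(i) to N(i+4) (carbonyl-to-acceptor direction of the alpha-helical
#' hydrogen-bond register), which runs N-terminus to C-terminus.
#'
#' @param chain a [chain_structure()].
#' @param segment inclusive `(start, end)` 0-based residue range, length >= 5.
#' @return An object of class `HelixAxis`: unit `direction` and the `segment`.
#' @export
helix_axis <- function(chain, segment) {
  start <- segment[1]; end <- segment[2]
  if (end - start + 1L < 5L) stop("helix too short: axis needs >= 5 residues")
  vs <- matrix(0, 0, 3)
  for (i in start:(end - 4L)) {
    O <- residue_atom(get_residue(chain, i), "O")
    N <- residue_atom(get_residue(chain, i + 4L), "N")
    if (is.null(O)) stop(sprintf("missing backbone atom O in residue %d", i))
    if (is.null(N)) stop(sprintf("missing backbone atom N in residue %d", i + 4L))
    vs <- rbind(vs, unit_vector(N - O))
  }
  structure(list(direction = unit_vector(colMeans(vs)),
                 segment = c(start, end)),
            class = "HelixAxis")
}

#' Inter-helical tilt angle between two helix axes
#'
#' Arc-cosine of the dot product of the (oriented) unit axes, in degrees,
#' range \[0, 180\]; orientation is preserved, not folded to \[0, 90\].
#'
#' @param axis_a,axis_b [helix_axis()] objects or unit 3-vectors.
#' @return Angle in degrees.
#' @export
interhelical_tilt <- function(axis_a, axis_b) {
  a <- if (inherits(axis_a, "HelixAxis")) axis_a$direction else axis_a
  b <- if (inherits(axis_b, "HelixAxis")) axis_b$direction else axis_b
  vector_angle(a, b)
}

#' Relative residue distance features of a pair
#'
#' `d1_mean`: mean Euclidean distance over all M x N heavy-atom pairs;
#' `d1_sd`: population standard deviation (divisor MN) of those distances;
#' `d_alpha`: the C-alpha to C-alpha distance.
#'
#' @param a,b [residue()] objects.
#' @return Named numeric vector `c(d1_mean, d1_sd, d_alpha)`.
#' @export
pair_distance_features <- function(a, b) {
  if (!nrow(a$coords) || !nrow(b$coords)) stop("no atoms: residue has zero heavy atoms")
  D <- sqrt(cross_dist2(a$coords, b$coords))
  ca_a <- residue_atom(a, "CA"); ca_b <- residue_atom(b, "CA")
  if (is.null(ca_a) || is.null(ca_b)) stop("missing alpha carbon")
  m <- mean(D)
  c(d1_mean = m, d1_sd = sqrt(mean((D - m)^2)),
    d_alpha = sqrt(sum((ca_a - ca_b)^2)))
}

#' Normal of a residue's plane
#'
#' The plane is spanned by the vectors (N - CA) and (C - CA); the normal is
#' their normalized cross product, in that fixed order.
#'
#' @param r a [residue()] with N, CA and C atoms.
#' @return Unit 3-vector.
#' @export
residue_plane_normal <- function(r) {
  N <- residue_atom(r, "N"); CA <- residue_atom(r, "CA"); C <- residue_atom(r, "C")
  if (is.null(N) || is.null(CA) || is.null(C))
    stop("missing backbone atom: residue plane needs N, CA, C")
  n <- cross3(N - CA, C - CA)
  if (sqrt(sum(n * n)) < 1e-9) stop("degenerate plane: N, CA, C are collinear")
  unit_vector(n)
}

#' Relative residue angle between two residue planes
#'
#' Angle between the plane normals of the two residues, degrees in \[0, 180\];
#' symmetric in its arguments.
#'
#' @param a,b [residue()] objects with N, CA, C.
#' @return Angle in degrees.
#' @export
relative_residue_angle <- function(a, b) {
  vector_angle(residue_plane_normal(a), residue_plane_normal(b))
}

# which annotated segment hosts residue i (0 if none)
segment_of <- function(ann, i) {
  hit <- which(ann$segments[, 1] <= i & i <= ann$segments[, 2])
  if (length(hit)) hit[1] else 0L
}

incomplete_neighborhood <- function(msg) {
  stop(structure(class = c("incomplete_neighborhood", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# the 4 pair-local SDF components for one (possibly off-helix) neighbor pair
sdf_pair_components <- function(chain, i, j) {
  n <- n_residues(chain)
  if (i < 0 || j < 0 || i >= n || j >= n)
    incomplete_neighborhood(sprintf("neighbor (%d,%d) outside chain", i, j))
  a <- get_residue(chain, i); b <- get_residue(chain, j)
  ok <- tryCatch({
    d <- pair_distance_features(a, b)
    delta <- relative_residue_angle(a, b)
    c(d, delta = delta)
  }, error = function(e)
    incomplete_neighborhood(sprintf("neighbor (%d,%d): %s", i, j, conditionMessage(e))))
  ok
}

#' Structurally derived feature vector of one residue pair (length 40)
#'
#' Concatenates, over the 8 neighbor positions of the 3x3 window around
#' (i, j) in fixed row-major order ((-1,-1), (-1,0), (-1,1), (0,-1), (0,1),
#' (1,-1), (1,0), (1,1)), the 5-vector (theta, d1_mean, d1_sd, d_alpha,
#' delta). Theta is the tilt between the two helices hosting the CENTER pair
#' and is therefore identical across the 8 positions; neighbors may fall off
#' the annotated helices (loop residues) but must exist and carry N, CA, C, O
#' atoms, otherwise an `incomplete_neighborhood` error is raised.
#'
#' @param chain a [chain_structure()].
#' @param ann a [helix_annotation()].
#' @param pair one-row data.frame (or list) with `i`, `j`, `helix_i`,
#'   `helix_j`.
#' @param axes optional precomputed list of [helix_axis()] per segment.
#' @return Numeric vector of length 40.
#' @export
sdf_vector <- function(chain, ann, pair, axes = NULL) {
  if (is.null(axes))
    axes <- lapply(seq_len(nrow(ann$segments)), function(s)
      helix_axis(chain, ann$segments[s, ]))
  theta <- interhelical_tilt(axes[[pair$helix_i]], axes[[pair$helix_j]])
  out <- numeric(0)
  for (w in seq_len(nrow(WINDOW_OFFSETS))) {
    comp <- sdf_pair_components(chain, pair$i + WINDOW_OFFSETS[w, 1],
                                pair$j + WINDOW_OFFSETS[w, 2])
    out <- c(out, theta, comp)
  }
  names(out) <- paste0(rep(sprintf("w%d", 1:8), each = 5),
                       c(".theta", ".d1_mean", ".d1_sd", ".d_alpha", ".delta"))
  out
}

# N, CA, O, CB coordinates of one residue (glycine: CB slot gets CA)
cf_residue_block <- function(r) {
  need <- lapply(c("N", "CA", "O"), function(nm) residue_atom(r, nm))
  if (any(vapply(need, is.null, TRUE)))
    incomplete_neighborhood(sprintf("residue %d lacks N/CA/O", r$seq_index))
  cb <- residue_atom(r, "CB") %||% need[[2]]
  c(need[[1]], need[[2]], need[[3]], cb)
}

#' Raw-coordinate feature vector of one residue pair (length 192)
#'
#' Per neighbor pair of the same 3x3 window as [sdf_vector()], 24 numbers:
#' for each of the two residues the x, y, z of N, CA, O, CB in that order
#' (glycine contributes its CA in the CB slot). Not rigid-motion invariant by
#' construction; this is the baseline the derived features are compared to.
#'
#' @param chain a [chain_structure()].
#' @param pair one-row data.frame (or list) with `i`, `j`.
#' @return Numeric vector of length 192.
#' @export
cf_vector <- function(chain, pair) {
  n <- n_residues(chain)
  out <- numeric(0)
  for (w in seq_len(nrow(WINDOW_OFFSETS))) {
    i <- pair$i + WINDOW_OFFSETS[w, 1]; j <- pair$j + WINDOW_OFFSETS[w, 2]
    if (i < 0 || j < 0 || i >= n || j >= n)
      incomplete_neighborhood(sprintf("neighbor (%d,%d) outside chain", i, j))
    out <- c(out, cf_residue_block(get_residue(chain, i)),
             cf_residue_block(get_residue(chain, j)))
  }
  unname(out)
}

#' Assemble the feature matrix of a chain's candidate pairs
#'
#' Loops over candidate pairs, skipping (and counting) pairs whose 3x3 window
#' leaves the chain or hits residues with missing required atoms; pair-local
#' components are cached so overlapping windows are computed once.
#'
#' @param chain a [chain_structure()].
#' @param ann a [helix_annotation()].
#' @param pairs data.frame from [candidate_pairs()].
#' @param kind `"SDF"` (length 40) or `"CF"` (length 192).
#' @param sequence_id identifier stored with the matrix.
#' @return An object of class `FeatureMatrix`: `x` (numeric matrix), `pairs`
#'   (rows actually featurized), `kept` (row indices into the input pairs),
#'   `kind`, `sequence_id`, `n_skipped`, and logical `scaled`.
#' @export
build_feature_matrix <- function(chain, ann, pairs, kind = c("SDF", "CF"),
                                 sequence_id = chain$chain_id) {
  kind <- match.arg(kind)
  width <- if (kind == "SDF") 40L else 192L
  axes <- if (kind == "SDF")
    lapply(seq_len(nrow(ann$segments)), function(s)
      helix_axis(chain, ann$segments[s, ])) else NULL
  cache <- new.env(parent = emptyenv())
  L <- n_residues(chain)
  pair_comp <- function(i, j) {   # cached 4-vector for SDF
    key <- as.character(i * L + j)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- sdf_pair_components(chain, i, j)
      cache[[key]] <- v
    }
    v
  }
  theta_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(pairs))
  kept <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    res <- tryCatch({
      if (kind == "SDF") {
        tk <- paste(pairs$helix_i[k], pairs$helix_j[k])
        theta <- theta_cache[[tk]]
        if (is.null(theta)) {
          theta <- interhelical_tilt(axes[[pairs$helix_i[k]]],
                                     axes[[pairs$helix_j[k]]])
          theta_cache[[tk]] <- theta
        }
        v <- numeric(0)
        for (w in seq_len(nrow(WINDOW_OFFSETS)))
          v <- c(v, theta, pair_comp(pairs$i[k] + WINDOW_OFFSETS[w, 1],
                                     pairs$j[k] + WINDOW_OFFSETS[w, 2]))
        unname(v)
      } else {
        cf_vector(chain, pairs[k, ])
      }
    }, incomplete_neighborhood = function(e) NULL)
    if (!is.null(res)) { rows[[k]] <- res; kept[k] <- TRUE }
  }
  n_skipped <- sum(!kept)
  if (!any(kept)) stop("no pair has a complete 3x3 neighborhood")
  x <- do.call(rbind, rows[kept])
  stopifnot(ncol(x) == width)
  structure(list(x = x, pairs = pairs[kept, , drop = FALSE],
                 kept = which(kept), kind = kind, sequence_id = sequence_id,
                 n_skipped = n_skipped, scaled = FALSE),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("<FeatureMatrix %s | %s | %d pairs x %d features | %d skipped%s>\n",
              x$sequence_id, x$kind, nrow(x$x), ncol(x$x), x$n_skipped,
              if (x$scaled) " | scaled" else ""))
  invisible(x)
}

#' Fit the per-feature min/max scaler
#'
#' Scaling maps each feature f to `-1 + 2 (f - min) / (max - min)` using the
#' minima/maxima of the TRAINING matrix only; applied test values are not
#' clipped and may fall outside \[-1, 1\]. Constant training columns map to 0.
#'
#' @param train a `FeatureMatrix` or plain numeric matrix.
#' @return An object of class `ScalingParams` (`min`, `max`, `kind`).
#' @export
fit_scaler <- function(train) {
  x <- if (inherits(train, "FeatureMatrix")) train$x else train
  stopifnot(is.matrix(x), nrow(x) >= 1)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max),
                 kind = if (inherits(train, "FeatureMatrix")) train$kind else NA),
            class = "ScalingParams")
}

#' @rdname fit_scaler
#' @param params a `ScalingParams`.
#' @param m a `FeatureMatrix` or plain matrix to scale.
#' @return The scaled object (same class as `m`).
#' @export
apply_scaler <- function(params, m) {
  x <- if (inherits(m, "FeatureMatrix")) m$x else m
  rng <- params$max - params$min
  const <- rng <= 0
  rng[const] <- 1
  xs <- sweep(sweep(x, 2, params$min, "-"), 2, rng, "/") * 2 - 1
  xs[, const] <- 0
  if (inherits(m, "FeatureMatrix")) { m$x <- xs; m$scaled <- TRUE; m } else xs
}

#' Read / write the tab-separated FeatureMatrix format
#'
#' A 3-column key (`sequence_id`, `i`, `j`) followed by the 40 or 192
#' feature columns.
#'
#' @param fm a `FeatureMatrix`.
#' @param path file path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sequence_id = fm$sequence_id, i = fm$pairs$i, j = fm$pairs$j)
  x <- fm$x
  colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  write.table(cbind(df, as.data.frame(x)), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c(sequence_id = "character"))
  x <- as.matrix(df[, grep("^f[0-9]+$", names(df)), drop = FALSE])
  dimnames(x) <- NULL
  kind <- if (ncol(x) == 40) "SDF" else if (ncol(x) == 192) "CF" else
    stop("feature file width is neither 40 (SDF) nor 192 (CF)")
  pairs <- df[, c("i", "j")]
  if (!is.null(df$helix_i)) pairs <- df[, c("i", "j", "helix_i", "helix_j")]
  structure(list(x = x, pairs = pairs, kept = seq_len(nrow(x)), kind = kind,
                 sequence_id = df$sequence_id[1], n_skipped = NA_integer_,
                 scaled = FALSE),
            class = "FeatureMatrix")
}

#' Read / write ScalingParams as a 2-row (min, max) table
#'
#' @param params a `ScalingParams`.
#' @param path file path.
#' @export
write_scaling_params <- function(params, path) {
  m <- rbind(min = params$min, max = params$max)
  write.table(m, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_scaling_params
#' @export
read_scaling_params <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", row.names = 1))
  structure(list(min = unname(m["min", ]), max = unname(m["max", ]),
                 kind = if (ncol(m) == 40) "SDF" else if (ncol(m) == 192) "CF" else NA),
            class = "ScalingParams")
}
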