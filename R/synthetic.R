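# Idealized alpha-helical bundle generator: full backbone + CB heavy atoms,
# known helix annotations, controllable packing geometry, Gaussian coordinate
# perturbation and an optional random global pose for the "predicted" member.
# Fixtures for the train-on-experimental / test-on-predicted protocol; they
# test mechanics, not biology (no side chains beyond CB, no membrane).

# cylindrical placement (radius A, phase offset deg, z offset A) of each atom
# relative to the CA of its residue, for an ideal helix with 1.5 A rise and
# 100 degree twist per residue about the +z axis
HELIX_ATOM_PARAMS <- list(
  N  = c(1.61, -28.3, -0.91),
  CA = c(2.30,   0.0,  0.00),
  C  = c(1.64,  21.0,  1.05),
  O  = c(1.64,  21.0,  2.28),   # carbonyl oxygen ~1.23 A above C, along the axis
  CB = c(3.60,  -6.0, -0.60)
)

#' Generate an ideal alpha-helix fragment
#'
#' Backbone (N, CA, C, O) plus CB placed on a cylinder with 1.5 Angstrom rise
#' and 100 degree twist per residue about the +z axis; the hydrogen-bond
#' register O(i) -> N(i+4) runs nearly parallel to the axis, which is what the
#' axis estimator exploits. The true axis (0, 0, 1) is recorded in the
#' `true_axis` attribute for oracle tests.
#'
#' @param n_res number of residues (>= 5).
#' @param aa one-letter code used for all residues (default poly-alanine).
#' @return A [chain_structure()] fragment with attribute `true_axis`.
#' @export
ideal_helix <- function(n_res, aa = "A") {
  if (n_res < 5) stop("an ideal helix needs at least 5 residues")
  coords <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    phi0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    m <- t(vapply(HELIX_ATOM_PARAMS, function(p) {
      a <- phi0 + p[2] * pi / 180
      c(p[1] * cos(a), p[1] * sin(a), z0 + p[3])
    }, numeric(3)))
    rownames(m) <- names(HELIX_ATOM_PARAMS)
    coords[[i]] <- m
  }
  out <- chain_structure("A",
                         data.frame(seq_index = 0:(n_res - 1L),
                                    author_number = 1:n_res,
                                    aa = rep(aa, n_res)),
                         coords, "experimental")
  attr(out, "true_axis") <- c(0, 0, 1)
  out
}

#' Bundle geometry specification
#'
#' @param n_helices number of helices (>= 2).
#' @param residues_per_helix residues per helix (>= 8).
#' @param inter_axial_distance spacing between adjacent helix axes, Angstrom.
#' @param crossing_angle angle by which adjacent (antiparallel) axes deviate
#'   from exactly 180 degrees.
#' @param loop_length unannotated residues joining consecutive helices.
#' @param seed RNG seed for the global pose jitter.
#' @return A `BundleSpec` list.
#' @export
bundle_spec <- function(n_helices = 2L, residues_per_helix = 14L,
                        inter_axial_distance = 9, crossing_angle = 20,
                        loop_length = 4L, seed = 1L) {
  stopifnot(n_helices >= 2, residues_per_helix >= 8,
            is.finite(inter_axial_distance), is.finite(crossing_angle),
            loop_length >= 1)
  structure(list(n_helices = as.integer(n_helices),
                 residues_per_helix = as.integer(residues_per_helix),
                 inter_axial_distance = inter_axial_distance,
                 crossing_angle = crossing_angle,
                 loop_length = as.integer(loop_length),
                 seed = as.integer(seed)),
            class = "BundleSpec")
}

# fixed local offsets giving loop residues a non-degenerate N/CA/C/O/CB tripod
LOOP_OFFSETS <- rbind(N = c(-0.7, 0.9, 0.5), CA = c(0, 0, 0),
                      C = c(0.8, 0.8, -0.4), O = c(1.1, 0.3, 0.4),
                      CB = c(0.2, -1.2, 0.6))

#' Generate an idealized multi-helix bundle
#'
#' Helices are placed side by side at the requested inter-axial distance,
#' alternating antiparallel, each tilted by half the crossing angle about the
#' packing direction, and joined by short unannotated loops. The whole bundle
#' then receives a seeded random rigid pose plus a 0.01 Angstrom coordinate
#' jitter (breaks exact distance ties without affecting geometry). At
#' inter-axial distances <= 9 Angstrom the 5.5 Angstrom contact rule yields
#' inter-helical contacts; at >= 25 Angstrom it yields none.
#'
#' @param spec a [bundle_spec()].
#' @return list with `chain` (a [chain_structure()], attribute `true_axes`)
#'   and `annotation` (a [helix_annotation()] marking the helical segments).
#' @export
helix_bundle <- function(spec) {
  stopifnot(inherits(spec, "BundleSpec"))
  nh <- spec$n_helices; nres <- spec$residues_per_helix
  helix_len <- (nres - 1) * 1.5
  frag <- ideal_helix(nres)

  res_coords <- list(); res_aa <- character(0)
  segments <- matrix(0L, 0, 2)
  axes <- list()
  prev_end_ca <- NULL
  for (h in seq_len(nh)) {
    Rflip <- if (h %% 2 == 0) rotation_matrix(c(1, 0, 0), 180) else diag(3)
    Rtilt <- rotation_matrix(c(1, 0, 0),
                             (if (h %% 2 == 0) -1 else 1) * spec$crossing_angle / 2)
    R <- Rtilt %*% Rflip
    shift <- c((h - 1) * spec$inter_axial_distance, 0, -helix_len / 2)
    hc <- lapply(frag$coords, function(m) {
      out <- sweep(m, 2, c(0, 0, helix_len / 2), "-") %*% t(R)
      out <- sweep(out, 2, c(shift[1], 0, 0), "+")
      rownames(out) <- rownames(m)
      out
    })
    axes[[h]] <- drop(R %*% c(0, 0, 1))
    if (!is.null(prev_end_ca)) {
      # unannotated loop linearly bridging the previous helix end
      first_ca <- hc[[1]]["CA", ]
      for (k in seq_len(spec$loop_length)) {
        f <- k / (spec$loop_length + 1)
        ca <- prev_end_ca * (1 - f) + first_ca * f + c(0, 3.5, 0)
        m <- sweep(LOOP_OFFSETS, 2, ca, "+")
        res_coords[[length(res_coords) + 1L]] <- m
        res_aa <- c(res_aa, "A")
      }
    }
    segments <- rbind(segments,
                      c(length(res_coords), length(res_coords) + nres - 1L))
    res_coords <- c(res_coords, hc)
    res_aa <- c(res_aa, frag$residues$aa)
    prev_end_ca <- hc[[nres]]["CA", ]
  }

  n <- length(res_coords)
  chain <- chain_structure("A",
                           data.frame(seq_index = 0:(n - 1L),
                                      author_number = 1:n, aa = res_aa),
                           res_coords, "experimental")
  posed <- with_seed(spec$seed, {
    R <- random_rotation(); t <- runif(3, -15, 15)
    ch <- transform_chain(chain, R, t)
    ch$coords <- lapply(ch$coords, function(m) {
      out <- m + matrix(rnorm(length(m), 0, 0.01), nrow(m), 3)
      rownames(out) <- rownames(m)
      out
    })
    attr(ch, "true_axes") <- lapply(axes, function(a) drop(R %*% a))
    ch
  })
  list(chain = posed, annotation = helix_annotation(segments))
}

#' Coordinate noise specification
#'
#' @param sigma isotropic Gaussian standard deviation per coordinate,
#'   Angstrom (>= 0; 0 reproduces the input exactly).
#' @param seed RNG seed.
#' @return A `NoiseSpec` list.
#' @export
noise_spec <- function(sigma, seed = 1L) {
  if (sigma < 0) stop("noise sigma must be non-negative")
  structure(list(sigma = sigma, seed = as.integer(seed)), class = "NoiseSpec")
}

#' Perturb every heavy-atom coordinate with Gaussian noise
#'
#' Emulates the coordinate error of a predicted structure: independent
#' Gaussian noise with standard deviation `noise$sigma` on every coordinate;
#' the result is tagged `"predicted"`. `sigma = 0` is the identity.
#'
#' @param chain a [chain_structure()].
#' @param noise a [noise_spec()].
#' @return The perturbed chain.
#' @export
perturb_coordinates <- function(chain, noise) {
  stopifnot(inherits(chain, "ChainStructure"), inherits(noise, "NoiseSpec"))
  out <- with_seed(noise$seed, {
    chain$coords <- lapply(chain$coords, function(m) {
      p <- m + matrix(rnorm(length(m), 0, noise$sigma), nrow(m), 3)
      rownames(p) <- rownames(m)
      p
    })
    chain
  })
  out$source_tag <- "predicted"
  out
}

#' Generate a paired synthetic benchmark
#'
#' `n_sequences` bundles with geometry drawn from the given ranges; each
#' clean "experimental" chain is paired with a "predicted" surrogate obtained
#' by Gaussian perturbation and (by default) an additional random rigid global
#' pose, emulating a structure predicted by a separate program in its own
#' arbitrary coordinate frame.
#'
#' @param n_sequences number of paired chains.
#' @param n_helices_range,residues_range,spacing_range,crossing_range
#'   inclusive ranges the per-sequence bundle parameters are drawn from.
#' @param noise a [noise_spec()]; its seed is combined with the per-sequence
#'   index.
#' @param seed master seed for the parameter draws.
#' @param loop_length loop residues between helices.
#' @param random_pose apply a random rigid transform to the predicted member.
#' @return list of entries `list(id, experimental, predicted, annotation)`,
#'   with attribute `contact_ratios`.
#' @export
make_benchmark <- function(n_sequences = 10L,
                           n_helices_range = c(2L, 4L),
                           residues_range = c(12L, 16L),
                           spacing_range = c(8, 10),
                           crossing_range = c(12, 24),
                           noise = noise_spec(0.5),
                           seed = 1L, loop_length = 4L,
                           random_pose = TRUE) {
  out <- vector("list", n_sequences)
  crs <- numeric(n_sequences)
  for (s in seq_len(n_sequences)) {
    sub <- (as.integer(seed) * 131L + s * 7919L) %% 2000000000L
    pick <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    pars <- with_seed(sub, list(
      nh = pick(n_helices_range),
      nres = pick(residues_range),
      d = runif(1, spacing_range[1], spacing_range[2]),
      ca = runif(1, crossing_range[1], crossing_range[2])))
    bnd <- helix_bundle(bundle_spec(pars$nh, pars$nres, pars$d, pars$ca,
                                    loop_length, seed = sub + 1L))
    pred <- perturb_coordinates(bnd$chain, noise_spec(noise$sigma, sub + 2L))
    if (random_pose)
      pred <- with_seed(sub + 3L,
                        transform_chain(pred, random_rotation(), runif(3, -30, 30)))
    cm <- label_contacts(bnd$chain, candidate_pairs(bnd$chain, bnd$annotation))
    crs[s] <- if (nrow(cm$pairs)) sum(cm$labels) / nrow(cm$pairs) else NA_real_
    out[[s]] <- list(id = sprintf("syn%02d", s), experimental = bnd$chain,
                     predicted = pred, annotation = bnd$annotation)
  }
  message(sprintf("benchmark: %d sequences, contact ratio %.3f-%.3f (median %.3f)",
                  n_sequences, min(crs), max(crs), stats::median(crs)))
  attr(out, "contact_ratios") <- crs
  out
}
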