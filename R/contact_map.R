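# Candidate inter-helical pair enumeration, binary contact labelling under the
# minimum heavy-atom distance rule, and the contact ratio.

#' Minimum heavy-atom distance between two residues
#'
#' The least Euclidean distance over all pairs of heavy atoms of the two
#' residues; the quantity the contact definition thresholds.
#'
#' @param a,b [residue()] objects (or coordinate matrices).
#' @return Distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(a, b) {
  A <- if (inherits(a, "Residue")) a$coords else a
  B <- if (inherits(b, "Residue")) b$coords else b
  if (!nrow(A) || !nrow(B)) stop("no atoms: residue has zero heavy atoms")
  sqrt(min(cross_dist2(A, B)))
}

#' Enumerate inter-helical candidate residue pairs
#'
#' All pairs (i, j), i < j, with the two residues on distinct annotated TM
#' helices and sequence separation `|i - j| > min_separation`. Ordering is
#' deterministic: ascending i, then j.
#'
#' @param chain a [chain_structure()] (bounds check only).
#' @param ann a [helix_annotation()] on the chain.
#' @param min_separation pairs must satisfy `|i - j| >` this (default 5).
#' @return data.frame with columns `i`, `j`, `helix_i`, `helix_j`.
#' @export
candidate_pairs <- function(chain, ann, min_separation = 5L) {
  seg <- ann$segments
  if (any(seg[, 2] >= n_residues(chain)))
    stop("annotation segment exceeds chain length")
  out <- list()
  ns <- nrow(seg)
  for (a in seq_len(ns)) {
    for (b in seq_len(ns)) {
      if (b <= a) next
      g <- expand.grid(i = seg[a, 1]:seg[a, 2], j = seg[b, 1]:seg[b, 2])
      g <- g[abs(g$i - g$j) > min_separation, , drop = FALSE]
      if (nrow(g)) {
        g$helix_i <- a; g$helix_j <- b
        out[[length(out) + 1L]] <- g
      }
    }
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0),
                      helix_i = integer(0), helix_j = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$i, res$j), ]
  rownames(res) <- NULL
  res
}

#' Construct a ContactMap
#'
#' @param pairs data.frame as returned by [candidate_pairs()].
#' @param labels binary vector (0/1), one per pair.
#' @param scores optional finite real-valued scores, one per pair.
#' @return An object of class `ContactMap`.
#' @export
contact_map <- function(pairs, labels, scores = NULL) {
  stopifnot(is.data.frame(pairs), length(labels) == nrow(pairs))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (!is.null(scores)) {
    stopifnot(length(scores) == nrow(pairs))
    if (!all(is.finite(scores))) stop("scores must be finite")
  }
  structure(list(pairs = pairs, labels = labels, scores = scores),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("<ContactMap | %d pairs | %d contacts%s>\n",
              nrow(x$pairs), sum(x$labels),
              if (is.null(x$scores)) "" else " | scored"))
  invisible(x)
}

#' Label candidate pairs as contacts
#'
#' A pair is a contact iff its minimum heavy-atom distance is strictly below
#' `threshold` (default 5.5 Angstrom).
#'
#' @param chain a [chain_structure()].
#' @param pairs data.frame from [candidate_pairs()].
#' @param threshold contact distance threshold in Angstrom.
#' @return A [contact_map()] with binary labels.
#' @export
label_contacts <- function(chain, pairs, threshold = 5.5) {
  lab <- integer(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    d <- min_heavy_atom_distance(get_residue(chain, pairs$i[k]),
                                 get_residue(chain, pairs$j[k]))
    lab[k] <- as.integer(d < threshold)
  }
  contact_map(pairs, lab)
}

#' Contact ratio of a contact map
#'
#' CR = number of contact points / number of candidate residue pair positions.
#'
#' @param cm a [contact_map()].
#' @return list with `n_pairs`, `n_contacts`, `contact_ratio`.
#' @export
contact_ratio <- function(cm) {
  stopifnot(inherits(cm, "ContactMap"))
  n <- nrow(cm$pairs)
  if (n == 0) stop("contact ratio undefined for an empty contact map")
  list(n_pairs = n, n_contacts = sum(cm$labels),
       contact_ratio = sum(cm$labels) / n)
}

#' Read / write the tab-separated ContactMap format
#'
#' Columns `i`, `j`, `label`, `score` (score `NA` when absent), 0-based
#' indices, with a header line.
#'
#' @param cm a [contact_map()].
#' @param path file path.
#' @export
write_contact_map <- function(cm, path) {
  df <- data.frame(i = cm$pairs$i, j = cm$pairs$j, label = cm$labels,
                   score = if (is.null(cm$scores)) NA_real_ else cm$scores)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  scores <- if (all(is.na(df$score))) NULL else df$score
  contact_map(df[, c("i", "j")], df$label, scores)
}
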