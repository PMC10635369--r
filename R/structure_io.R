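# PDB coordinate I/O, the chain data model, TM-helix annotations, and
# reconciliation of paired experimental/predicted structures.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

#' Construct a ChainStructure
#'
#' The in-memory model of one protein chain: an ordered set of residues, each
#' holding named heavy atoms with 3-d coordinates in Angstrom. Residues are
#' indexed by a contiguous, 0-based `seq_index`; the author residue numbering
#' from the coordinate file is retained only for I/O and offset handling.
#'
#' @param chain_id chain identifier (single string).
#' @param residues data.frame with columns `seq_index`, `author_number`, `aa`
#'   (one-letter code).
#' @param coords list (one entry per residue, in `seq_index` order) of
#'   numeric matrices with 3 columns and atom names as row names.
#' @param source_tag `"experimental"` or `"predicted"`.
#' @return An object of class `ChainStructure`.
#' @export
chain_structure <- function(chain_id, residues, coords,
                            source_tag = c("experimental", "predicted")) {
  source_tag <- match.arg(source_tag)
  stopifnot(is.data.frame(residues), nrow(residues) >= 1,
            length(coords) == nrow(residues))
  if (!identical(residues$seq_index, 0:(nrow(residues) - 1L)))
    stop("seq_index must be contiguous 0-based integers")
  for (m in coords) {
    if (!is.matrix(m) || ncol(m) != 3 || !all(is.finite(m)))
      stop("each residue needs an (n x 3) finite coordinate matrix")
    if (anyDuplicated(rownames(m))) stop("duplicate atom names within a residue")
  }
  structure(list(chain_id = chain_id, residues = residues, coords = coords,
                 source_tag = source_tag),
            class = "ChainStructure")
}

#' @export
print.ChainStructure <- function(x, ...) {
  cat(sprintf("<ChainStructure %s | %d residues | %d atoms | %s>\n",
              x$chain_id, nrow(x$residues),
              sum(vapply(x$coords, nrow, 1L)), x$source_tag))
  invisible(x)
}

n_residues <- function(chain) nrow(chain$residues)

#' Extract one residue from a chain
#'
#' @param chain a [chain_structure()].
#' @param i 0-based `seq_index`.
#' @return A `Residue` object: heavy-atom coordinate matrix (`coords`, atom
#'   names as row names), one-letter `aa`, `seq_index` and `author_number`.
#' @export
get_residue <- function(chain, i) {
  if (i < 0 || i >= n_residues(chain)) stop(sprintf("residue %d not in chain", i))
  residue(chain$coords[[i + 1L]], aa = chain$residues$aa[i + 1L],
          seq_index = i, author_number = chain$residues$author_number[i + 1L])
}

#' Construct a bare Residue
#'
#' @param coords numeric matrix (atoms x 3) with atom names as row names.
#' @param aa one-letter amino-acid code.
#' @param seq_index,author_number optional indices.
#' @return A `Residue` object.
#' @export
residue <- function(coords, aa = "A", seq_index = NA_integer_,
                    author_number = NA_integer_) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  structure(list(coords = coords, aa = aa, seq_index = seq_index,
                 author_number = author_number), class = "Residue")
}

residue_atom <- function(r, name) {
  k <- match(name, rownames(r$coords))
  if (is.na(k)) NULL else r$coords[k, ]
}

# element symbol inferred from a PDB atom name when columns 77-78 are blank
infer_element <- function(atom_name) {
  s <- gsub("[^A-Za-z]", "", atom_name)
  if (nchar(s) == 0) return("")
  toupper(substr(s, 1, 1))
}

#' Parse ATOM records of a PDB-format string into a ChainStructure
#'
#' Reads fixed-column ATOM records for one chain (first model only, HETATM
#' ignored). Hydrogens are discarded; for alternate locations of the same atom
#' the record with the highest occupancy is kept (ties: first encountered).
#'
#' @param text PDB-format text (single string or character vector of lines).
#' @param chain_id chain identifier to extract.
#' @param source_tag stored on the result; see [chain_structure()].
#' @return A [chain_structure()].
#' @export
parse_pdb_coordinates <- function(text, chain_id,
                                  source_tag = c("experimental", "predicted")) {
  source_tag <- match.arg(source_tag)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  sel <- grepl("^ATOM  ", lines) & substr(lines, 22, 22) == chain_id
  lines <- lines[sel]
  if (!length(lines)) stop(sprintf("empty chain: no ATOM records for chain '%s'", chain_id))

  fld <- function(a, b) trimws(substr(lines, a, b))
  name <- fld(13, 16); altloc <- substr(lines, 17, 17)
  resname <- fld(18, 20); resseq <- fld(23, 26); icode <- substr(lines, 27, 27)
  xs <- fld(31, 38); ys <- fld(39, 46); zs <- fld(47, 54); occ <- fld(55, 60)
  elem <- fld(77, 78)

  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    stop(sprintf("malformed coordinate field in ATOM line: %s", lines[bad[1]]))
  occv <- suppressWarnings(as.numeric(occ)); occv[!is.finite(occv)] <- 1

  element <- ifelse(elem == "", vapply(name, infer_element, ""), toupper(elem))
  heavy <- !(element %in% c("H", "D"))
  if (!any(heavy)) stop(sprintf("empty chain: only hydrogens for chain '%s'", chain_id))

  key <- paste(resseq, icode, sep = "|")[heavy]
  name <- name[heavy]; resname <- resname[heavy]
  xyz <- cbind(x, y, z)[heavy, , drop = FALSE]
  occv <- occv[heavy]; resseq <- resseq[heavy]

  ukeys <- unique(key)  # file order
  res_list <- vector("list", length(ukeys))
  meta <- data.frame(seq_index = seq_along(ukeys) - 1L,
                     author_number = integer(length(ukeys)),
                     aa = character(length(ukeys)))
  for (k in seq_along(ukeys)) {
    idx <- which(key == ukeys[k])
    # altloc resolution: per atom name keep highest occupancy, ties first
    keep <- idx[order(match(name[idx], unique(name[idx])), -occv[idx],
                      seq_along(idx))]
    keep <- keep[!duplicated(name[keep])]
    keep <- keep[order(match(keep, idx))]
    m <- xyz[keep, , drop = FALSE]
    rownames(m) <- name[keep]
    res_list[[k]] <- m
    meta$author_number[k] <- as.integer(resseq[idx[1]])
    meta$aa[k] <- unname(AA3TO1[resname[idx[1]]] %||% "X")
    if (is.na(meta$aa[k])) meta$aa[k] <- "X"
  }
  chain_structure(chain_id, meta, res_list, source_tag)
}

#' Write a ChainStructure as fixed-column PDB ATOM records
#'
#' @param chain a [chain_structure()].
#' @return A single PDB-format string (ATOM records, TER, END), coordinates
#'   at 3 decimals, residues in `seq_index` order.
#' @export
write_pdb_coordinates <- function(chain) {
  stopifnot(inherits(chain, "ChainStructure"))
  out <- character(0)
  serial <- 0L
  for (k in seq_len(n_residues(chain))) {
    m <- chain$coords[[k]]
    res3 <- AA1TO3[chain$residues$aa[k]] %||% "UNK"
    if (is.na(res3)) res3 <- "UNK"
    for (a in seq_len(nrow(m))) {
      nm <- rownames(m)[a]
      if (nchar(nm) > 4) stop(sprintf("atom name '%s' longer than 4 characters", nm))
      serial <- serial + 1L
      # names shorter than 4 chars start in column 14 (PDB convention)
      namefld <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
      out <- c(out, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namefld, res3, chain$chain_id,
        chain$residues$author_number[k], m[a, 1], m[a, 2], m[a, 3],
        1.00, 0.00, infer_element(nm)))
    }
  }
  paste(c(out, "TER", "END", ""), collapse = "\n")
}

#' @rdname parse_pdb_coordinates
#' @param path file path.
#' @export
read_pdb <- function(path, chain_id,
                     source_tag = c("experimental", "predicted")) {
  parse_pdb_coordinates(readLines(path, warn = FALSE), chain_id,
                        match.arg(source_tag))
}

#' @rdname write_pdb_coordinates
#' @param path file path.
#' @export
write_pdb <- function(chain, path) {
  writeLines(write_pdb_coordinates(chain), path, sep = "")
  invisible(path)
}

#' Construct a transmembrane-helix annotation
#'
#' @param segments a 2-column matrix or list of length-2 vectors of inclusive
#'   0-based `(start, end)` residue index ranges. Segments must be sorted,
#'   non-overlapping, and at least 5 residues long (the minimum for helix-axis
#'   estimation).
#' @return An object of class `HelixAnnotation`.
#' @export
helix_annotation <- function(segments) {
  if (is.list(segments)) segments <- do.call(rbind, segments)
  segments <- matrix(as.integer(segments), ncol = 2)
  colnames(segments) <- c("start", "end")
  if (nrow(segments) == 0) stop("annotation needs at least one segment")
  if (any(segments[, 2] - segments[, 1] + 1L < 5L))
    stop("every TM segment must span at least 5 residues")
  if (is.unsorted(segments[, 1], strictly = TRUE))
    stop("segments must be sorted by start")
  if (nrow(segments) > 1 &&
      any(segments[-1, 1] <= segments[-nrow(segments), 2]))
    stop("segments must be non-overlapping")
  structure(list(segments = segments), class = "HelixAnnotation")
}

#' @export
print.HelixAnnotation <- function(x, ...) {
  cat(sprintf("<HelixAnnotation | %d segments | L = %d>\n",
              nrow(x$segments), annotation_length(x)))
  invisible(x)
}

#' Total concatenated TM-helix length L of an annotation
#'
#' @param ann a [helix_annotation()].
#' @return Integer sum of annotated segment lengths.
#' @export
annotation_length <- function(ann) {
  sum(ann$segments[, 2] - ann$segments[, 1] + 1L)
}

#' Read / write the plain-text annotation format
#'
#' One segment per line, whitespace-separated inclusive 0-based
#' `start end`; `#` starts a comment.
#'
#' @param path file path.
#' @return [read_helix_annotation()] returns a [helix_annotation()].
#' @export
read_helix_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("no segments in annotation file %s", path))
  seg <- t(vapply(strsplit(lines, "[[:space:]]+"), function(p) {
    if (length(p) != 2) stop("annotation lines must be 'start end'")
    as.integer(p)
  }, integer(2)))
  helix_annotation(seg)
}

#' @rdname read_helix_annotation
#' @param ann a [helix_annotation()].
#' @export
write_helix_annotation <- function(ann, path) {
  writeLines(c("# start end (inclusive, 0-based seq_index)",
               sprintf("%d %d", ann$segments[, 1], ann$segments[, 2])), path)
  invisible(path)
}

#' Reconcile an experimental/predicted structure pair
#'
#' Verifies, residue by residue over all annotated TM segments, that adding
#' `offset` to the experimental author numbering lands on a predicted residue
#' with the same amino acid. Chains whose TM zones are not contiguously and
#' identically present in both members are rejected ("partial match"), the
#' rule used to filter paired datasets.
#'
#' @param exp experimental [chain_structure()].
#' @param pred predicted [chain_structure()].
#' @param offset integer added to experimental author numbers to match
#'   predicted author numbers.
#' @param annotation [helix_annotation()] on the experimental chain's
#'   `seq_index` space.
#' @return An object of class `PairedStructure` with a `map` vector giving,
#'   for each experimental `seq_index` (1-based position in the vector), the
#'   0-based predicted `seq_index` or `NA` outside the common span.
#' @export
reconcile_pair <- function(exp, pred, offset, annotation) {
  stopifnot(inherits(exp, "ChainStructure"), inherits(pred, "ChainStructure"),
            inherits(annotation, "HelixAnnotation"))
  pred_by_author <- match(exp$residues$author_number + as.integer(offset),
                          pred$residues$author_number)
  map <- pred$residues$seq_index[pred_by_author]  # NA where absent
  for (s in seq_len(nrow(annotation$segments))) {
    idx <- annotation$segments[s, 1]:annotation$segments[s, 2]
    if (any(idx >= n_residues(exp)))
      stop("annotation segment exceeds experimental chain")
    pm <- map[idx + 1L]
    if (anyNA(pm))
      stop(sprintf("partial match: TM segment %d not contiguously present in predicted chain", s))
    if (any(diff(pm) != 1L))
      stop(sprintf("partial match: TM segment %d not contiguous in predicted chain", s))
    if (!identical(exp$residues$aa[idx + 1L], pred$residues$aa[pm + 1L]))
      stop(sprintf("partial match: amino-acid mismatch in TM segment %d", s))
  }
  structure(list(experimental = exp, predicted = pred,
                 offset = as.integer(offset), annotation = annotation,
                 map = map),
            class = "PairedStructure")
}

#' Translate experimental-frame residue pairs to the predicted chain
#'
#' @param paired a [reconcile_pair()] result.
#' @param pairs data.frame of pairs (`i`, `j`) in experimental `seq_index`.
#' @return The same data.frame with `i`, `j` rewritten in predicted
#'   `seq_index`; errors if any pair falls outside the common span.
#' @export
translate_pairs <- function(paired, pairs) {
  i2 <- paired$map[pairs$i + 1L]; j2 <- paired$map[pairs$j + 1L]
  if (anyNA(i2) || anyNA(j2))
    stop("pair outside the common span of the paired structures")
  pairs$i <- i2; pairs$j <- j2
  pairs
}

#' Annotation translated into the predicted chain's seq_index space
#'
#' @param paired a [reconcile_pair()] result.
#' @return A [helix_annotation()] in predicted coordinates.
#' @export
translate_annotation <- function(paired) {
  seg <- paired$annotation$segments
  helix_annotation(cbind(paired$map[seg[, 1] + 1L], paired$map[seg[, 2] + 1L]))
}

#' Apply a rigid-body transform to every atom of a chain
#'
#' @param chain a [chain_structure()].
#' @param R 3x3 rotation matrix (default identity).
#' @param t length-3 translation vector (default zero).
#' @return The transformed chain.
#' @export
transform_chain <- function(chain, R = diag(3), t = c(0, 0, 0)) {
  chain$coords <- lapply(chain$coords, function(m) {
    out <- m %*% t(R)
    out <- sweep(out, 2, t, "+")
    rownames(out) <- rownames(m)
    out
  })
  chain
}
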