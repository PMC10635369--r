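# Fixtures are built in code; nothing is stored on disk.

# residue with arbitrary named heavy atoms
res_fix <- function(..., aa = "A", seq_index = 0L) {
  atoms <- list(...)
  m <- do.call(rbind, atoms)
  rownames(m) <- names(atoms)
  residue(m, aa = aa, seq_index = seq_index)
}

# a residue with a complete N/CA/C/O/CB tripod centered at `at`
full_res <- function(at = c(0, 0, 0), aa = "A", seq_index = 0L) {
  res_fix(N = at + c(-1.2, 0.5, 0), CA = at, C = at + c(1.0, 0.8, -0.3),
          O = at + c(1.4, 1.9, -0.2), CB = at + c(0.2, -1.1, 0.9),
          aa = aa, seq_index = seq_index)
}

# minimal hand-written PDB text: rows of (resseq, name, x, y, z, occ, altloc,
# element); resname ALA unless given
pdb_text <- function(rows, chain = "A") {
  lines <- character(0)
  for (k in seq_len(nrow(rows))) {
    r <- rows[k, ]
    nm <- r$name
    namefld <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
    lines <- c(lines, sprintf(
      "ATOM  %5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, namefld, r$altloc, r$resname %||% "ALA", chain, r$resseq,
      r$x, r$y, r$z, r$occ, 0.0, r$element))
  }
  paste(c(lines, "END", ""), collapse = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pdb_row <- function(resseq, name, x, y, z, occ = 1, altloc = " ",
                    element = substr(name, 1, 1), resname = "ALA") {
  data.frame(resseq = resseq, name = name, x = x, y = y, z = z, occ = occ,
             altloc = altloc, element = element, resname = resname,
             stringsAsFactors = FALSE)
}

# a small two-helix bundle reused across test files
two_helix_chain <- function(d = 8.5, nres = 14, seed = 3) {
  helix_bundle(bundle_spec(2, nres, d, 20, 4, seed = seed))
}

# a deterministic random rotation without touching the global RNG
seeded_rotation <- function(seed) {
  with_seed(seed, {
    axis <- rnorm(3)
    rotation_matrix(axis, runif(1, 0, 360))
  })
}

# features + labels entries for model/evaluate tests
benchmark_entries <- function(ds, kind = "SDF") {
  lapply(ds, function(e) {
    pairs <- candidate_pairs(e$experimental, e$annotation)
    cm <- label_contacts(e$experimental, pairs)
    fme <- build_feature_matrix(e$experimental, e$annotation, pairs, kind, e$id)
    fmp <- build_feature_matrix(e$predicted, e$annotation, pairs, kind, e$id)
    stopifnot(identical(fme$kept, fmp$kept))
    pcm <- label_contacts(e$predicted, pairs)
    list(id = e$id, features = fme, features_test = fmp,
         labels = cm$labels[fme$kept], pred_labels = pcm$labels[fme$kept],
         L = annotation_length(e$annotation))
  })
}
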