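#' Protein chain objects
#'
#' A `protein_chain` is the minimal structural unit used throughout the
#' package: a one-letter amino-acid sequence together with the alpha-carbon
#' (CA) trace, one 3-vector per residue, in Angstrom. Residues declared in a
#' full-length sequence record (SEQRES / entity sequence) but lacking a CA
#' atom are not stored as rows; their count is kept in `n_unmodelled` so
#' dataset filters can reason about completeness.
#'
#' @param chain_id single-character string naming the chain.
#' @param sequence one-letter amino-acid string of length L (unknown residues
#'   are `"X"`).
#' @param ca_coords numeric L x 3 matrix of CA coordinates in Angstrom.
#' @param n_unmodelled non-negative count of residues present in the declared
#'   sequence but without coordinates.
#' @return An object of class `protein_chain`.
#' @examples
#' ch <- protein_chain("A", "GA", rbind(c(0, 0, 0), c(3.8, 0, 0)))
#' chain_length(ch)
#' @export
protein_chain <- function(chain_id, sequence, ca_coords, n_unmodelled = 0L) {
  ca_coords <- as.matrix(ca_coords)
  storage.mode(ca_coords) <- "double"
  x <- structure(list(chain_id = as.character(chain_id),
                      sequence = as.character(sequence),
                      ca_coords = ca_coords,
                      n_unmodelled = as.integer(n_unmodelled)),
                 class = "protein_chain")
  validate_protein_chain(x)
}

validate_protein_chain <- function(x) {
  L <- nchar(x$sequence)
  if (L < 1L) se_stop("validation_error", "chain '%s': empty sequence", x$chain_id)
  if (!is.matrix(x$ca_coords) || ncol(x$ca_coords) != 3L)
    se_stop("validation_error", "chain '%s': ca_coords must be an L x 3 matrix", x$chain_id)
  if (nrow(x$ca_coords) != L)
    se_stop("validation_error",
            "chain '%s': %d coordinate rows for %d sequence residues",
            x$chain_id, nrow(x$ca_coords), L)
  if (!all(is.finite(x$ca_coords)))
    se_stop("validation_error", "chain '%s': non-finite coordinates", x$chain_id)
  if (x$n_unmodelled < 0L)
    se_stop("validation_error", "chain '%s': negative n_unmodelled", x$chain_id)
  x
}

#' @rdname protein_chain
#' @param x a `protein_chain`.
#' @export
chain_length <- function(x) nchar(x$sequence)

#' @export
print.protein_chain <- function(x, ...) {
  cat(sprintf("<protein_chain '%s'> L = %d, unmodelled = %d\n",
              x$chain_id, chain_length(x), x$n_unmodelled))
  invisible(x)
}

#' Multimeric assembly objects
#'
#' An `assembly` is an ordered list of [protein_chain] objects with unique
#' chain identifiers, representing a quaternary structure.
#'
#' @param assembly_id string naming the assembly.
#' @param chains list of `protein_chain` objects (at least one).
#' @return An object of class `assembly`.
#' @export
assembly <- function(assembly_id, chains) {
  if (length(chains) < 1L) se_stop("validation_error", "assembly needs at least one chain")
  for (ch in chains) {
    if (!inherits(ch, "protein_chain"))
      se_stop("validation_error", "all elements of 'chains' must be protein_chain objects")
    validate_protein_chain(ch)
  }
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids))
    se_stop("validation_error", "duplicate chain ids: %s",
            paste(ids[duplicated(ids)], collapse = ", "))
  names(chains) <- ids
  structure(list(assembly_id = as.character(assembly_id), chains = chains),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s'> %d chain(s)\n", x$assembly_id, length(x$chains)))
  for (ch in x$chains)
    cat(sprintf("  %s: L = %d, unmodelled = %d\n",
                ch$chain_id, chain_length(ch), ch$n_unmodelled))
  invisible(x)
}

aa3to1 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

#' Read a macromolecular structure file
#'
#' Parses a PDB or mmCIF file (via bio3d) into an [assembly] of CA-only
#' [protein_chain]s. Only polymer ATOM records contribute; waters, ligands
#' and other HETATM entities are ignored. For alternate locations the
#' first-listed conformer is kept; residues are ordered as listed in the
#' file. mmCIF chains are identified by `auth_asym_id` (bio3d's chain
#' column). When a full-length SEQRES record is present for a chain, residues
#' in SEQRES without a CA atom are counted in `n_unmodelled`; otherwise
#' `n_unmodelled` is 0.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` map to mmCIF, anything else to PDB).
#' @return An [assembly] with one chain per polymer chain that has at least
#'   one CA atom.
#' @seealso [write_structure()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) se_stop("parse_error", "file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) se_stop("parse_error", "cannot parse '%s': %s", path, conditionMessage(e))
  )
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) se_stop("empty_structure_error", "no alpha-carbon atoms in '%s'", path)
  # first-listed altloc conformer per residue, residues in file order
  key <- paste(ca$chain, ca$resno, ca$insert %|na|% "")
  ca <- ca[!duplicated(key), , drop = FALSE]
  seqres <- pdb$seqres
  chains <- list()
  for (cid in unique(ca$chain)) {
    sub <- ca[ca$chain == cid, , drop = FALSE]
    seq1 <- paste(aa3to1(sub$resid), collapse = "")
    n_unmod <- 0L
    if (!is.null(seqres) && cid %in% names(seqres)) {
      declared <- sum(names(seqres) == cid)
      n_unmod <- max(0L, declared - nrow(sub))
    }
    chains[[cid]] <- protein_chain(cid, seq1,
                                   cbind(sub$x, sub$y, sub$z),
                                   n_unmodelled = n_unmod)
  }
  assembly(basename(path), chains)
}

`%|na|%` <- function(x, y) { x[is.na(x)] <- y; x }

#' Write an assembly as a CA-only PDB file
#'
#' Writes one ATOM record per residue (CA atoms only), chains labelled by
#' their `chain_id` and separated by TER records, so that
#' `read_structure(write_structure(a))` reproduces coordinates within PDB
#' fixed-point precision (1e-3 Angstrom).
#'
#' @param asm an [assembly] (a single [protein_chain] is also accepted).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(asm, path) {
  if (inherits(asm, "protein_chain")) asm <- assembly(asm$chain_id, list(asm))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) se_stop("io_error", "cannot write '%s': directory does not exist", path)
  xyz <- do.call(rbind, lapply(asm$chains, `[[`, "ca_coords"))
  seqs <- lapply(asm$chains, function(ch) strsplit(ch$sequence, "")[[1]])
  resid3 <- unlist(lapply(seqs, function(s) {
    r <- bio3d::aa123(s); r[s == "X"] <- "UNK"; r
  }), use.names = FALSE)
  chain <- rep(vapply(asm$chains, function(ch) substr(ch$chain_id, 1, 1), ""),
               vapply(asm$chains, chain_length, 0L))
  resno <- unlist(lapply(asm$chains, function(ch) seq_len(chain_length(ch))),
                  use.names = FALSE)
  tryCatch(
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     type = rep("ATOM", nrow(xyz)), resno = resno,
                     resid = resid3, eleno = seq_len(nrow(xyz)),
                     elety = rep("CA", nrow(xyz)), chain = chain,
                     chainter = TRUE, end = TRUE),
    error = function(e) se_stop("io_error", "cannot write '%s': %s", path, conditionMessage(e))
  )
  invisible(path)
}

#' Dataset inclusion filter for protein chains
#'
#' A chain passes when its length strictly exceeds `min_length` amino acids
#' and it has strictly fewer than `max_unmodelled` structurally unmodelled
#' residues — the inclusion rule used to assemble non-redundant full-chain
#' benchmark sets.
#'
#' @param chain a [protein_chain].
#' @param min_length length threshold (default 200; inclusion requires L > 200).
#' @param max_unmodelled unmodelled-residue threshold (default 20; inclusion
#'   requires fewer than 20).
#' @return `TRUE` or `FALSE`.
#' @export
passes_chain_filter <- function(chain, min_length = 200L, max_unmodelled = 20L) {
  validate_protein_chain(chain)
  chain_length(chain) > min_length && chain$n_unmodelled < max_unmodelled
}
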