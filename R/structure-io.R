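#' Read a protein model from PDB or mmCIF
#'
#' The format is auto-detected from the file extension (`.cif`/`.mmcif` vs
#' anything else) with a content fallback: files whose first records look
#' like CIF (`data_`/`loop_`) are parsed as mmCIF. Altloc labels and
#' occupancies are preserved exactly as on disk; blank altloc and insertion
#' codes are normalized to `""`.
#'
#' @param path file path to a PDB or mmCIF model
#' @return a [ProteinModel-class]
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- readLines(path, n = 50L, warn = FALSE)
  if (!length(txt) || !any(nzchar(trimws(txt))))
    stop("parse error: ", path, " is empty")
  isCif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE) ||
    any(grepl("^(data_|loop_|_atom_site)", txt))
  pdb <- if (isCif) {
    tryCatch(suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                              verbose = FALSE)),
             error = function(e) stop("parse error in mmCIF file ", path,
                                      ": ", conditionMessage(e)))
  } else {
    if (!any(grepl("^(ATOM|HETATM)", txt)) &&
        !any(grepl("^(ATOM|HETATM)", readLines(path, warn = FALSE))))
      stop("parse error: no ATOM/HETATM records in ", path)
    tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
             error = function(e) stop("parse error in PDB file ", path,
                                      ": ", conditionMessage(e)))
  }
  a <- pdb$atom[, .ATOM_COLS]
  a$alt[is.na(a$alt)] <- ""
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  rownames(a) <- NULL
  methods::new("ProteinModel", atoms = a)
}

#' Write a protein model to PDB or mmCIF
#'
#' PDB output uses fixed columns (coordinates at 3 decimals, occupancy and B
#' at 2); mmCIF output is a minimal `_atom_site` loop. Round-tripping through
#' [readStructure()] reproduces coordinates to format precision and altlocs
#' and occupancies exactly.
#'
#' @param x a [ProteinModel-class]
#' @param path output file path
#' @param format `"pdb"` or `"mmcif"` (default guessed from the extension,
#'   falling back to PDB)
#' @return `path`, invisibly
#' @export
writeStructure <- function(x, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(is(x, "ProteinModel"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  a <- x@atoms
  if (format == "pdb") {
    lines <- sprintf(
      "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$type, a$eleno %% 100000L, .pdbAtomName(a$elety, a$elesy),
      ifelse(a$alt == "", " ", a$alt), a$resid, a$chain, a$resno,
      ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, a$o, a$b,
      a$elesy)
    writeLines(c(lines, "END"), path)
  } else {
    # canonical wwPDB atom_site column order
    hdr <- c("data_multiconf", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    rows <- sprintf(
      "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
      a$type, a$eleno, a$elesy, a$elety,
      ifelse(a$alt == "", ".", a$alt), a$resid, a$chain, a$resno,
      ifelse(a$insert == "", "?", a$insert), a$x, a$y, a$z, a$o, a$b,
      a$resno, a$resid, a$chain, a$elety)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

# PDB columns 13-16: element right-justified in 13-14 for 1-2 char elements;
# 4-char names fill the field.
.pdbAtomName <- function(elety, elesy) {
  out <- character(length(elety))
  for (i in seq_along(elety)) {
    nm <- elety[i]
    out[i] <- if (nchar(nm) >= 4L) substr(nm, 1, 4)
      else if (nchar(elesy[i]) == 2L) sprintf("%-4s", nm)
      else sprintf(" %-3s", nm)
  }
  out
}

#' @rdname stripAltConfs
#' @details For each group of atoms sharing a (residue, atom name) with
#'   non-blank altlocs, the conformer with the highest occupancy is kept
#'   (ties broken toward the altloc label earliest in the alphabet); the
#'   surviving atom gets a blank label and occupancy 1. Altloc-free input is
#'   returned unchanged, so the operation is idempotent.
#' @export
setMethod("stripAltConfs", "ProteinModel", function(x) {
  a <- x@atoms
  if (!nrow(a) || all(a$alt == "")) return(x)
  grp <- paste(a$chain, a$resno, a$insert, a$elety)
  keep <- rep(TRUE, nrow(a))
  for (g in unique(grp[a$alt != ""])) {
    idx <- which(grp == g)
    alt <- idx[a$alt[idx] != ""]
    if (!length(alt)) next
    # pick highest occupancy, tie -> alphabetically earliest altloc
    best <- alt[order(-a$o[alt], a$alt[alt])][1]
    drop <- setdiff(alt, best)
    keep[drop] <- FALSE
    a$alt[best] <- ""
    a$o[best] <- 1
  }
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  a$eleno <- seq_len(nrow(a))
  methods::new("ProteinModel", atoms = a)
})

# residue keys and per-residue atom extraction used across the pipeline
.resKey <- function(a) paste(a$chain, a$resno, a$insert, sep = ":")

.proteinResidues <- function(a) {
  a <- a[a$resid %in% .STD_AA & a$type == "ATOM", , drop = FALSE]
  unique(a[, c("chain", "resno", "insert", "resid")])
}
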