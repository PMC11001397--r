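#' Flexibility census of a model
#'
#' Counts the distinct altloc labels per standard amino-acid residue
#' (blank-only residues count as one conformer) and computes the flexible
#' fraction: residues with two or more conformers over all protein residues.
#' Waters, ligands and ions (HETATM / non-standard residues) are excluded
#' from the denominator.
#'
#' @param x a [ProteinModel-class]
#' @return a [FlexibilityCensus-class]
#' @export
flexibilityCensus <- function(x) {
  stopifnot(is(x, "ProteinModel"))
  a <- x@atoms
  a <- a[a$resid %in% .STD_AA & a$type == "ATOM", , drop = FALSE]
  res <- unique(a[, c("chain", "resno", "insert", "resid")])
  key <- paste(a$chain, a$resno, a$insert, sep = ":")
  counts <- vapply(seq_len(nrow(res)), function(i) {
    k <- paste(res$chain[i], res$resno[i], res$insert[i], sep = ":")
    labs <- unique(a$alt[key == k])
    max(1L, length(setdiff(labs, "")))
  }, 1L)
  res$conformers <- counts
  rownames(res) <- NULL
  flex <- paste(res$chain, res$resno, res$insert, sep = ":")[counts >= 2L]
  frac <- if (nrow(res)) length(flex) / nrow(res) else 0
  methods::new("FlexibilityCensus", counts = res, flexible = flex,
               fraction = frac)
}

#' Compare the flexible-residue sets of two censuses
#'
#' Splits the union of the two flexible sets into three disjoint groups:
#' residues flexible in both models, only in the first and only in the
#' second (the two-set overlap summary).
#'
#' @param a,b [FlexibilityCensus-class] objects over the same chain/residue
#'   numbering
#' @return list with character vectors `shared`, `onlyA`, `onlyB` and their
#'   sizes `nShared`, `nOnlyA`, `nOnlyB`
#' @export
compareCensus <- function(a, b) {
  stopifnot(is(a, "FlexibilityCensus"), is(b, "FlexibilityCensus"))
  shared <- intersect(a@flexible, b@flexible)
  onlyA <- setdiff(a@flexible, b@flexible)
  onlyB <- setdiff(b@flexible, a@flexible)
  list(shared = shared, onlyA = onlyA, onlyB = onlyB,
       nShared = length(shared), nOnlyA = length(onlyA),
       nOnlyB = length(onlyB))
}

#' Write a census (and optional comparison) to JSON and CSV
#'
#' @param census a [FlexibilityCensus-class]
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>.csv`
#' @param comparison optional result of [compareCensus()] folded into the
#'   JSON
#' @return character vector of the written paths, invisibly
#' @export
writeCensus <- function(census, prefix, comparison = NULL) {
  csv <- paste0(prefix, ".csv")
  json <- paste0(prefix, ".json")
  utils::write.csv(census@counts, csv, row.names = FALSE)
  payload <- list(
    n_residues = nrow(census@counts),
    n_flexible = length(census@flexible),
    flexible_fraction = census@fraction,
    conformer_histogram = as.list(table(census@counts$conformers)),
    flexible_residues = census@flexible)
  if (!is.null(comparison))
    payload$comparison <- comparison[c("nShared", "nOnlyA", "nOnlyB",
                                       "shared", "onlyA", "onlyB")]
  jsonlite::write_json(payload, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(json, csv))
}

#' Bar plot of alternate-conformer counts per residue
#'
#' @param census a [FlexibilityCensus-class]
#' @param ... passed to [graphics::barplot()]
#' @return invisibly, NULL
#' @export
plotCensus <- function(census, ...) {
  tab <- table(factor(census@counts$conformers,
                      levels = seq_len(max(census@counts$conformers, 1))))
  graphics::barplot(tab, xlab = "conformers per residue",
                    ylab = "residues", ...)
  invisible(NULL)
}
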