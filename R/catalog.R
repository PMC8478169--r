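# The copper-system model catalog: which profile HMM accession belongs to
# which resistance system. Categories form a closed four-element set.

CATEGORY_LEVELS <- c("Cue", "Cus", "CopPco", "Multisystem")

#' Default catalog of copper-associated profile HMM accessions
#'
#' Seventeen TIGRFAM/COG/Pfam accessions mapped to the four copper-resistance
#' categories. Models whose reference proteins span more than one system
#' (CueO/PcoA/CopA-oxidase; the CusS/PcoS/CopS sensor kinases; the
#' CusR/PcoR/CopR response regulators) are Multisystem. The Cu(I)-translocating
#' P-type ATPase model (COG2217) is carried under Cue, its chromosomal home
#' system in E. coli; being a plain data frame the catalog is one edit away
#' from any other grouping.
#'
#' @return `data.frame(model_accession, system_category, protein_labels)`.
#' @export
default_model_catalog <- function() {
  e <- function(acc, cat, labels) data.frame(
    model_accession = acc, system_category = cat, protein_labels = labels,
    stringsAsFactors = FALSE)
  cat <- rbind(
    e("TIGR02044", "Cue",         "CueR, E. coli"),
    e("TIGR01480", "Multisystem", "CueO, E. coli; PcoA, E. coli; CopA, P. syringae"),
    e("COG2217",   "Cue",         "CopA, E. coli"),
    e("TIGR01386", "Multisystem", "CusS, E. coli; PcoS, E. coli; CopS, P. syringae"),
    e("TIGR01387", "Multisystem", "CusR, E. coli; PcoR, E. coli; CopR, P. syringae"),
    e("COG3696",   "Cus",         "CusA, E. coli"),
    e("COG0845",   "Cus",         "CusB, E. coli"),
    e("TIGR01845", "Cus",         "CusC, E. coli"),
    e("COG5569",   "Cus",         "CusF, E. coli"),
    e("COG3667",   "CopPco",      "PcoB, E. coli; CopB, P. syringae"),
    e("COG2372",   "CopPco",      "PcoC, E. coli; CopC, P. syringae"),
    e("COG1276",   "CopPco",      "PcoD, E. coli; CopD, P. syringae"),
    e("PF11106.8", "CopPco",      "PcoE, E. coli; PcoF, E. coli"),
    e("COG0739",   "CopPco",      "PcoG, E. coli"),
    e("TIGR00003", "CopPco",      "CopZ, P. syringae"),
    e("TIGR02698", "CopPco",      "CopY, S. mutans"),
    e("COG1937",   "CopPco",      "CsoR, S. haemolyticus"))
  validate_model_catalog(cat)
}

#' Validate a model catalog
#'
#' Every accession must appear exactly once and every category must come from
#' the closed set Cue, Cus, CopPco, Multisystem.
#'
#' @param catalog A catalog data frame.
#' @return The catalog, invisibly usable; errors on violation.
#' @export
validate_model_catalog <- function(catalog) {
  need <- c("model_accession", "system_category")
  if (!all(need %in% names(catalog)))
    stop("catalog needs columns model_accession and system_category")
  if (anyDuplicated(catalog$model_accession))
    stop("catalog accessions must be unique: ",
         paste(unique(catalog$model_accession[duplicated(catalog$model_accession)]),
               collapse = ", "))
  bad <- setdiff(unique(catalog$system_category), CATEGORY_LEVELS)
  if (length(bad))
    stop("unknown system categories: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(CATEGORY_LEVELS, collapse = ", "), ")")
  catalog
}

#' Write / read a model catalog config (tab-delimited, one row per accession)
#'
#' @param catalog Catalog data frame.
#' @param path File path.
#' @return `path` (write) or the catalog (read).
#' @export
write_model_catalog <- function(catalog, path) {
  validate_model_catalog(catalog)
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_catalog
#' @export
read_model_catalog <- function(path) {
  validate_model_catalog(
    utils::read.delim(path, stringsAsFactors = FALSE))
}
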