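assay_roles <- c("or_target", "endogenous_ref", "oe_ref", "internal_control")
or_classes <- c("class_I", "class_II", "not_applicable")
smoking_levels <- c("never", "past", "current", "unknown")

#' Assay panel
#'
#' Per-assay metadata for a TaqMan array layout: gene symbol, role (OR
#' target, endogenous reference, olfactory-epithelium-specific reference, or
#' internal control), OR class (class I = the "fish-like" OR51/52/55/56
#' families), deorphanization status with the published agonist where known,
#' the potentially-non-functional flag (intact-looking genes whose known
#' haplotypes all mutate conserved motif positions), and whether the assay's
#' primers span an intron (identified by an `"_m"` suffix in the assay id).
#'
#' @param df data.frame with columns `assay_id`, `gene_symbol`, `role`, and
#'   optionally `or_class`, `deorphanized`, `agonist`,
#'   `potentially_nonfunctional`, `intron_spanning`, `excluded`. Missing
#'   `intron_spanning` is inferred from the `"_m"` assay-id suffix.
#' @return data.frame of class `assay_panel` with validated columns and an
#'   attribute `role_counts`.
#' @export
assay_panel <- function(df) {
  need <- c("assay_id", "gene_symbol", "role")
  if (!all(need %in% names(df)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$assay_id))
    stop("validation error: duplicated assay_id: ",
         paste(unique(df$assay_id[duplicated(df$assay_id)]), collapse = ", "))
  if (!all(df$role %in% assay_roles))
    stop("validation error: unknown role: ",
         paste(setdiff(df$role, assay_roles), collapse = ", "))
  df$or_class <- as.character(df$or_class %||%
                                ifelse(df$role == "or_target", "class_II", "not_applicable"))
  if (!all(df$or_class %in% or_classes))
    stop("validation error: unknown or_class")
  if (any(df$or_class != "not_applicable" & df$role != "or_target") ||
      any(df$or_class == "not_applicable" & df$role == "or_target"))
    stop("validation error: or_class must be not_applicable iff role != or_target")
  df$deorphanized <- as.logical(df$deorphanized %||% FALSE)
  df$agonist <- as.character(df$agonist %||% "")
  df$potentially_nonfunctional <- as.logical(df$potentially_nonfunctional %||% FALSE)
  inferred <- grepl("_m$", df$assay_id)
  isp <- if (is.null(df$intron_spanning)) rep(NA, nrow(df))
         else as.logical(df$intron_spanning)
  df$intron_spanning <- ifelse(is.na(isp), inferred, isp | inferred)
  df$excluded <- as.logical(df$excluded %||% FALSE)
  df <- df[c("assay_id", "gene_symbol", "role", "or_class", "deorphanized",
             "agonist", "potentially_nonfunctional", "intron_spanning",
             "excluded")]
  attr(df, "role_counts") <- table(factor(df$role, levels = assay_roles))
  class(df) <- c("assay_panel", "data.frame")
  df
}

#' @export
print.assay_panel <- function(x, ...) {
  rc <- attr(x, "role_counts")
  cat("assay_panel:", nrow(x), "assays (",
      paste(names(rc), rc, sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Read an assay panel from TSV
#'
#' @param path TSV with the columns documented in [assay_panel()].
#' @return an [assay_panel()]
#' @export
read_assay_panel <- function(path) {
  df <- read_tsv_plain(path, colClasses = "character")
  for (col in c("deorphanized", "potentially_nonfunctional",
                "intron_spanning", "excluded"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  assay_panel(df)
}

#' Write an assay panel to TSV
#' @param panel an [assay_panel()]
#' @param path output path
#' @export
write_assay_panel <- function(panel, path) {
  write_tsv_plain(as.data.frame(panel), path)
}

#' The packaged default 384-well panel layout
#'
#' 356 OR-target assays, 10 endogenous reference genes, the GAPDH internal
#' control and 6 olfactory-epithelium-specific reference genes. Reference
#' genes, the 47 deorphanized ORs and OR2A14 are real identifiers; the
#' remaining OR names are synthetic placeholders (subfamily letters X/Y/Z)
#' that reproduce the published composition: 54 class I ORs among the 355
#' analyzed, 52 potentially non-functional ORs, 4 intron-spanning `"_m"` OR
#' assays.
#'
#' @return an [assay_panel()]
#' @export
default_panel <- function() {
  read_assay_panel(extdata_path("default_panel_synthetic.tsv"))
}

#' Packaged fixture: the 47 deorphanized olfactory receptors
#'
#' Published agonist, mean RNA copies per 20 ng total RNA (mean and SD
#' across the 26-donor cohort) and the number of donors expressing each
#' receptor above the 5-copy cutoff.
#'
#' @return data.frame with columns `or_name`, `agonist`, `copies_mean`,
#'   `copies_sd`, `n_expressing` (47 rows).
#' @export
load_table2_fixture <- function() {
  df <- read_tsv_plain(extdata_path("table2_deorphanized.tsv"))
  stopifnot(nrow(df) == 47,
            all(df$n_expressing >= 0 & df$n_expressing <= 26))
  df
}

#' Packaged fixture: donor metadata for the 26-sample cohort
#'
#' Age (years), sex, RNA integrity number, smoking status
#' (never/past/current/unknown), cause of death, post-mortem delay (hours)
#' and geographic origin for each donor.
#'
#' @return data.frame with one row per donor (26 rows).
#' @export
load_sample_metadata <- function() {
  df <- read_tsv_plain(extdata_path("table1_metadata.tsv"),
                       colClasses = c(sample_id = "character"))
  stopifnot(nrow(df) == 26, all(df$rin >= 1 & df$rin <= 10),
            all(df$age > 0), all(df$smoking %in% smoking_levels))
  df
}
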