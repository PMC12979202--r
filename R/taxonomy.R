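#' Cell-class taxonomies
#'
#' The classifier emits one confidence value per cytological class (a "CMD"
#' vector). Two taxonomies are supported: the original 10-class set and the
#' extended 11-class set that adds navicular cells (glycogen-rich benign
#' squamous cells that can mimic LSIL and are common in younger donors).
#'
#' @param n_classes Either 10 or 11.
#' @return Character vector of class names, in canonical order.
#' @export
#' @examples
#' cyto_classes(11)
cyto_classes <- function(n_classes = 11) {
  n_classes <- as.integer(n_classes)
  base <- c(
    "leukocyte", "superficial_intermediate", "parabasal", "metaplasia",
    "glandular", "miscellaneous", "lsil", "hsil", "adenocarcinoma",
    "irrelevant"
  )
  if (n_classes == 10L) return(base)
  if (n_classes == 11L) return(c(base, "navicular"))
  stop("`n_classes` must be 10 or 11, got ", n_classes)
}

#' Bethesda reporting categories used for slide-level diagnosis
#'
#' @return Character vector: NILM, ASC-US, LSIL, ASC-H, HSIL, SCC.
#' @export
bethesda_categories <- function() {
  c("NILM", "ASC-US", "LSIL", "ASC-H", "HSIL", "SCC")
}

#' Lesion (abnormal) classes targeted by the per-cell gates
#' @return Character vector of the three lesion class names.
#' @export
lesion_classes <- function() c("lsil", "hsil", "adenocarcinoma")

#' Fallback (normal epithelial) classes for a taxonomy
#'
#' Classes assigned by argmax when no gate is crossed: everything except
#' irrelevant, leukocyte and the lesion classes.
#'
#' @param taxonomy Character vector of class names.
#' @return Character vector of fallback class names, in taxonomy order.
#' @export
fallback_classes <- function(taxonomy = cyto_classes(11)) {
  setdiff(taxonomy, c("irrelevant", "leukocyte", lesion_classes()))
}

# internal: names of the cmd_* columns for a taxonomy
cmd_cols <- function(taxonomy) paste0("cmd_", taxonomy)

# internal: names of the count_* columns for a taxonomy
count_cols <- function(taxonomy) paste0("count_", taxonomy)

# internal: validate that a cmd matrix/data frame covers the taxonomy exactly
check_cmd_schema <- function(cmd, taxonomy) {
  keys <- colnames(cmd)
  keys <- sub("^cmd_", "", keys)
  missing <- setdiff(taxonomy, keys)
  extra <- setdiff(keys, taxonomy)
  if (length(missing) || length(extra)) {
    stop(
      "CMD keys do not match the taxonomy",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", "))
    )
  }
  invisible(TRUE)
}
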