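#' The 13 organelle localization classes
#'
#' Canonical, fixed ordering of the 13 subcellular compartments a protein's
#' fluorescence signal can be annotated to: actin filaments (AF), centrosome
#' (CE), cytosol (CY), endoplasmic reticulum (ER), Golgi apparatus (GA),
#' intermediate filaments (IF), microtubules (MT), mitochondria (MC), nuclear
#' membrane (NM), nucleoli (NI), nucleus (NU), plasma membrane (PM) and
#' vesicles (VE).  Every 13-long confidence or label vector in the package
#' follows this ordering.
#'
#' @return Character vector of the 13 class codes in canonical order.
#' @export
#' @examples
#' organelle_classes()
organelle_classes <- function() {
  c("AF", "CE", "CY", "ER", "GA", "IF", "MT", "MC", "NM", "NI", "NU", "PM", "VE")
}

#' Number of localization classes
#' @return The integer 13.
#' @export
n_classes <- function() 13L

#' Build a binary label vector from class codes
#'
#' @param codes Character vector of class codes (subset of
#'   [organelle_classes()]), or a single space-separated string as stored in
#'   the `classes` column of `labels.csv`.
#' @return Named integer vector of length 13 with 1 for present classes.
#' @export
#' @examples
#' label_vector(c("NU", "CY"))
label_vector <- function(codes) {
  cls <- organelle_classes()
  if (length(codes) == 1 && grepl(" ", codes)) codes <- strsplit(codes, " +")[[1]]
  codes <- codes[nzchar(codes)]
  bad <- setdiff(codes, cls)
  if (length(bad)) stop("unknown class code(s): ", paste(bad, collapse = ", "))
  setNames(as.integer(cls %in% codes), cls)
}

#' Class codes present in a label vector
#' @param labels Binary 13-vector in canonical class order.
#' @return Character vector of present class codes.
#' @export
label_codes <- function(labels) {
  stopifnot(length(labels) == n_classes())
  organelle_classes()[labels > 0]
}
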