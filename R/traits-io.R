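#' Coerce to a specimen-by-trait matrix
#'
#' @param X Matrix or data frame with specimen rownames (or a first
#'   character column of labels) and numeric trait columns. Missing values
#'   stay `NA`.
#' @return Numeric matrix with unique specimen rownames.
#' @export
as_trait_matrix <- function(X) {
  if (is.matrix(X) && is.numeric(X)) {
    if (is.null(rownames(X))) stop("trait matrix needs specimen rownames")
  } else if (is.data.frame(X)) {
    if (!is.numeric(X[[1L]]) &&
        (is.null(rownames(X)) ||
         identical(rownames(X), as.character(seq_len(nrow(X)))))) {
      rn <- as.character(X[[1L]])
      X <- X[, -1L, drop = FALSE]
      rownames(X) <- rn
    }
    keep <- vapply(X, is.numeric, logical(1))
    X <- as.matrix(X[, keep, drop = FALSE])
  } else stop("cannot interpret 'X' as a trait matrix")
  if (anyDuplicated(rownames(X)))
    stop("duplicate specimen labels: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "),
         call. = FALSE)
  storage.mode(X) <- "double"
  bad <- is.infinite(X)
  if (any(bad)) stop("non-finite trait values present", call. = FALSE)
  X
}

#' Read a delimited specimen-by-trait table
#'
#' First column: specimen label; header row: trait names; comma or tab
#' delimited (sniffed from the header line); empty fields or `NA` mark
#' missing values.
#'
#' @param file Path to the table.
#' @return Numeric matrix with specimen rownames (see [as_trait_matrix()]).
#'   Non-numeric annotation columns are dropped with a message.
#' @export
read_trait_table <- function(file) {
  if (!file.exists(file)) stop("trait table not found: ", file, call. = FALSE)
  hdr <- readLines(file, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  d <- utils::read.table(file, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""), quote = "\"",
                         comment.char = "")
  num <- vapply(d[-1L], is.numeric, logical(1))
  if (any(!num))
    message("dropping non-numeric column(s): ",
            paste(names(d[-1L])[!num], collapse = ", "))
  as_trait_matrix(d[, c(1L, 1L + which(num)), drop = FALSE])
}

#' Write a trait matrix as delimited text
#' @param X Trait matrix (see [as_trait_matrix()]).
#' @param file Output path.
#' @param sep Field separator.
#' @return `file`, invisibly.
#' @export
write_trait_table <- function(X, file, sep = ",") {
  X <- as_trait_matrix(X)
  d <- data.frame(specimen = rownames(X), X, check.names = FALSE)
  utils::write.table(d, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Morphometric measurements of the Xylodon australis species complex
#'
#' Per-specimen mean basidia length/width and spore length/width (micrometres)
#' with the spore length/width ratio Q, for the 38 specimens of the
#' published morphological study: 22 accessions under the *X. australis*
#' name (holotype plus Australian CANB and New Zealand PDD collections),
#' the *X. lenis* isotype, and 15 *X. magallanesii* accessions from
#' Patagonia. `(-)` entries of the source table are `NA` here.
#'
#' @return A list with `traits` (38 x 5 numeric matrix: `basidia_L`,
#'   `basidia_W`, `spore_L`, `spore_W`, `spore_Q`), and `info` (data frame
#'   with `specimen`, `species`, `country`, plus logical helper columns
#'   `is_type` and the molecular-lineage assignment `clade`:
#'   `"Australia"` for Australian CANB material, `"Patagonia"` for
#'   *X. magallanesii*, `NA` for New Zealand specimens and the *X. lenis*
#'   isotype, which have no molecular placement).
#' @export
table1_fixture <- function() {
  f <- system.file("extdata", "xylodon_table1_traits.csv",
                   package = "morphoplace", mustWork = TRUE)
  d <- utils::read.csv(f, check.names = FALSE, stringsAsFactors = FALSE)
  traits <- as.matrix(d[, c("basidia_L", "basidia_W",
                            "spore_L", "spore_W", "spore_Q")])
  rownames(traits) <- d$specimen
  is_type <- grepl("type", d$specimen, ignore.case = TRUE)
  clade <- rep(NA_character_, nrow(d))
  clade[d$species == "Xylodon australis" & d$country == "Australia"] <-
    "Australia"
  clade[d$species == "Xylodon magallanesii"] <- "Patagonia"
  info <- data.frame(specimen = d$specimen, species = d$species,
                     country = d$country, is_type = is_type,
                     clade = clade, stringsAsFactors = FALSE)
  list(traits = traits, info = info)
}
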