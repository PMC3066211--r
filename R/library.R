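#' siRNA library table
#'
#' The arrayed library maps each siRNA duplex to the gene it targets and to
#' its physical placement (plate index and well address). Screens of this
#' design carry `sirnas_per_gene` (default 3) independent duplexes per gene,
#' each in its own well, so that hits can be required to be concordant across
#' sequences.
#'
#' @param entries data.frame with columns `sirna_id`, `gene`, `plate`, `well`
#'   and optionally `sequence`.
#' @param sirnas_per_gene expected number of duplexes per gene (r).
#' @param check if `TRUE` (default) a gene with a number of entries different
#'   from `sirnas_per_gene` is an error; `validate_screen()` can be used
#'   instead for a report-only check.
#' @return An object of class `sirna_library` (a data.frame).
#' @examples
#' lib <- sirna_library(data.frame(
#'   sirna_id = c("KIN1_s1", "KIN1_s2", "KIN1_s3"),
#'   gene = "KIN1", plate = 1, well = c("A1", "A2", "A3")))
#' @export
sirna_library <- function(entries, sirnas_per_gene = 3, check = TRUE) {
  need <- c("sirna_id", "gene", "plate", "well")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop_format("siRNA library lacks column(s): %s", paste(miss, collapse = ", "))
  entries <- as.data.frame(entries)
  entries$plate <- as.integer(entries$plate)
  if (anyDuplicated(entries$sirna_id))
    stop_validation("duplicate siRNA identifier(s): %s",
                    paste(unique(entries$sirna_id[duplicated(entries$sirna_id)]),
                          collapse = ", "))
  key <- paste(entries$plate, entries$well)
  if (anyDuplicated(key))
    stop_validation("more than one siRNA placed at plate/well: %s",
                    paste(unique(key[duplicated(key)]), collapse = ", "))
  if (check) {
    n <- table(entries$gene)
    bad <- names(n)[n != sirnas_per_gene]
    if (length(bad))
      stop_validation("gene(s) with != %d siRNAs: %s", sirnas_per_gene,
                      paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(entries, sirnas_per_gene = sirnas_per_gene,
            class = c("sirna_library", "data.frame"))
}

#' @export
print.sirna_library <- function(x, ...) {
  cat(sprintf("<sirna_library> %d siRNAs, %d genes, %d plates (r = %d)\n",
              nrow(x), length(unique(x$gene)), length(unique(x$plate)),
              attr(x, "sirnas_per_gene")))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Read / write an siRNA library table
#'
#' Delimited text with header `sirna_id`, `gene`, `plate`, `well` and
#' optionally `sequence`.
#'
#' @param path file path.
#' @param library an `sirna_library` (for writing).
#' @param sirnas_per_gene,check passed to [sirna_library()].
#' @export
read_sirna_library <- function(path, sirnas_per_gene = 3, check = TRUE) {
  df <- read_delimited(path, c("sirna_id", "gene", "plate", "well"))
  sirna_library(df, sirnas_per_gene = sirnas_per_gene, check = check)
}

#' @rdname read_sirna_library
#' @export
write_sirna_library <- function(library, path) {
  write_tsv(as.data.frame(library), path)
}

# Role of every (plate, well) actually in play: the layout template gives the
# per-plate role pattern; template sample wells not occupied by any library
# siRNA on a given plate are treated as empty there.
effective_wells <- function(layout, library) {
  plates <- sort(unique(library$plate))
  wells <- names(roles(layout))
  df <- data.frame(
    plate = rep(plates, each = length(wells)),
    well = rep(wells, length(plates)),
    role = rep(unname(roles(layout)), length(plates)),
    stringsAsFactors = FALSE)
  key <- paste(df$plate, df$well)
  lk <- paste(library$plate, library$well)
  idx <- match(key, lk)
  df$sirna_id <- library$sirna_id[idx]
  df$gene <- library$gene[idx]
  df$role[df$role == "sample" & is.na(df$sirna_id)] <- "empty"
  misplaced <- !is.na(df$sirna_id) & df$role != "sample"
  if (any(misplaced))
    stop_validation("siRNA placed on a non-sample well: %s",
                    paste(utils::head(key[misplaced], 5), collapse = ", "))
  df
}
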