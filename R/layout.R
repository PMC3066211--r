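#' Plate layout: geometry and role of every well
#'
#' A `plate_layout` records the geometry of a microtitre plate (rows are
#' lettered, columns numbered) and the role of each well: `"sample"` wells
#' carry library siRNAs, `"neg_control"` wells carry non-targeting siRNA or
#' transfection reagent only, `"pos_control"` wells carry an siRNA known to
#' abolish the reporter signal without affecting cell density, and `"empty"`
#' wells are unused. The default is the screen's 96-well design: negative
#' controls at A12, B12, G12, H12 and positive controls at G1, H1, everything
#' else a sample well.
#'
#' Well addresses are row letter plus 1-based column number with no leading
#' zeros ("A1", "A12").
#'
#' @param n_rows,n_cols plate geometry (default 8 x 12, rows A-H).
#' @param neg_control_wells,pos_control_wells,empty_wells well addresses for
#'   the non-sample roles; all remaining wells are samples.
#' @return An object of class `plate_layout`.
#' @examples
#' lay <- plate_layout()
#' table(roles(lay))
#' @export
plate_layout <- function(n_rows = 8, n_cols = 12,
                         neg_control_wells = c("A12", "B12", "G12", "H12"),
                         pos_control_wells = c("G1", "H1"),
                         empty_wells = character()) {
  if (n_rows < 1 || n_rows > 26 || n_cols < 1)
    stop_argument("plate geometry %dx%d is not supported", n_rows, n_cols)
  wells <- all_wells(n_rows, n_cols)
  special <- c(neg_control_wells, pos_control_wells, empty_wells)
  if (anyDuplicated(special))
    stop_validation("well addresses assigned to more than one role: %s",
                    paste(unique(special[duplicated(special)]), collapse = ", "))
  bad <- setdiff(special, wells)
  if (length(bad))
    stop_validation("well address out of plate bounds: %s",
                    paste(bad, collapse = ", "))
  role <- rep("sample", length(wells))
  names(role) <- wells
  role[neg_control_wells] <- "neg_control"
  role[pos_control_wells] <- "pos_control"
  role[empty_wells] <- "empty"
  structure(list(n_rows = n_rows, n_cols = n_cols, roles = role),
            class = "plate_layout")
}

#' All well addresses of a plate in row-major order
#'
#' @param n_rows,n_cols plate geometry, or a `plate_layout` as first argument.
#' @return Character vector "A1", "A2", ..., row-major.
#' @export
all_wells <- function(n_rows = 8, n_cols = 12) {
  if (inherits(n_rows, "plate_layout")) {
    lay <- n_rows
    n_rows <- lay$n_rows
    n_cols <- lay$n_cols
  }
  as.vector(t(outer(LETTERS[seq_len(n_rows)], seq_len(n_cols), paste0)))
}

#' Well roles of a layout
#' @param layout a `plate_layout`.
#' @return Named character vector mapping well address to role.
#' @export
roles <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  layout$roles
}

# Split "B7" into row index / column index; errors on malformed addresses
# (leading zeros are malformed: "A1", never "A01").
parse_well <- function(well, n_rows = 8, n_cols = 12) {
  m <- regmatches(well, regexec("^([A-Z])([1-9][0-9]*)$", well))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad))
    stop_validation("malformed well address: %s",
                    paste(unique(well[bad]), collapse = ", "))
  row <- match(vapply(m, `[`, "", 2L), LETTERS)
  col <- as.integer(vapply(m, `[`, "", 3L))
  if (any(row > n_rows | col > n_cols | col < 1))
    stop_validation("well address out of plate bounds: %s",
                    paste(unique(well[row > n_rows | col > n_cols | col < 1]),
                          collapse = ", "))
  list(row = row, col = col)
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d wells\n", x$n_rows, x$n_cols))
  tab <- table(x$roles)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Read / write a plate layout table
#'
#' Layout files are delimited text with columns `well` and `role`. Geometry is
#' inferred from the largest row letter and column number unless given.
#'
#' @param path file path.
#' @param layout a `plate_layout` (for writing).
#' @param n_rows,n_cols optional explicit geometry when reading.
#' @return `read_layout()` a `plate_layout`; `write_layout()` the path,
#'   invisibly.
#' @export
read_layout <- function(path, n_rows = NULL, n_cols = NULL) {
  df <- read_delimited(path, c("well", "role"))
  ok <- c("sample", "neg_control", "pos_control", "empty")
  if (!all(df$role %in% ok))
    stop_format("unknown well role(s): %s",
                paste(setdiff(unique(df$role), ok), collapse = ", "))
  if (anyDuplicated(df$well))
    stop_validation("duplicate well address in layout: %s",
                    paste(unique(df$well[duplicated(df$well)]), collapse = ", "))
  pw <- parse_well(df$well, 26, 1000)
  if (is.null(n_rows)) n_rows <- max(pw$row)
  if (is.null(n_cols)) n_cols <- max(pw$col)
  lay <- plate_layout(n_rows, n_cols,
                      neg_control_wells = df$well[df$role == "neg_control"],
                      pos_control_wells = df$well[df$role == "pos_control"],
                      empty_wells = df$well[df$role == "empty"])
  # wells absent from the file are empty, not sample
  missing <- setdiff(all_wells(lay), df$well)
  lay$roles[missing] <- "empty"
  lay
}

#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plate_layout"))
  df <- data.frame(well = names(layout$roles), role = unname(layout$roles))
  write_tsv(df, path)
}
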