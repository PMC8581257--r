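#' Lactation record table
#'
#' Validated repeated-records table: one row per 305-day lactation record
#' with its fixed-effect levels.  Columns: `animal_id`, `breed`,
#' `lactation_number` (integer in 1..3), `hys` (herd-year-season level),
#' `yield` (kg, strictly positive), `trait` tag.  Each animal has at most
#' three records with distinct lactation numbers.
#'
#' @param df Data frame with the columns above.
#' @return Object of class `lactation_records` (a data.frame).
#' @export
as_records <- function(df) {
  need <- c("animal_id", "breed", "lactation_number", "hys", "yield",
            "trait")
  if (!all(need %in% names(df))) {
    stop("records need columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$animal_id <- as.character(df$animal_id)
  df$breed <- as.character(df$breed)
  df$hys <- as.character(df$hys)
  df$lactation_number <- as.integer(df$lactation_number)
  if (any(!df$lactation_number %in% 1:3)) {
    stop("lactation_number outside {1,2,3}")
  }
  if (any(!is.finite(df$yield) | df$yield <= 0)) {
    stop("yields must be strictly positive and finite")
  }
  dup <- duplicated(df[, c("animal_id", "lactation_number")])
  if (any(dup)) {
    stop("duplicate lactation number for animal(s): ",
         paste(unique(df$animal_id[dup]), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("lactation_records", "data.frame"))
}

#' Read lactation phenotypes for one trait
#'
#' CSV columns: `animal_id`, `breed`, `lactation_number`, then either a
#' pre-concatenated `hys` column or the triplet `herd`, `year`, `season`
#' (joined with `_` into an opaque level), and yield columns `my_305`,
#' `fy_305`, `py_305` (only the requested trait's column is required).
#' Rows with a missing yield for the requested trait are dropped with a
#' logged count.
#'
#' @param path CSV file.
#' @param trait `"MY"`, `"FY"` or `"PY"`.
#' @return A [as_records()] table for the requested trait.
#' @export
read_phenotypes <- function(path, trait = c("MY", "FY", "PY")) {
  trait <- match.arg(trait)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ycol <- c(MY = "my_305", FY = "fy_305", PY = "py_305")[[trait]]
  if (!ycol %in% names(df)) {
    stop("phenotype file has no column ", ycol, " for trait ", trait)
  }
  if (!"hys" %in% names(df)) {
    if (all(c("herd", "year", "season") %in% names(df))) {
      df$hys <- paste(df$herd, df$year, df$season, sep = "_")
    } else {
      stop("phenotype file needs either a hys column or herd/year/season")
    }
  }
  y <- suppressWarnings(as.numeric(df[[ycol]]))
  drop <- is.na(y)
  if (any(drop)) {
    hb_log("phenotypes: dropped %d row(s) with missing %s", sum(drop), ycol)
  }
  df <- df[!drop, , drop = FALSE]
  if (nrow(df) == 0L) {
    hb_log("phenotypes: no usable records for trait %s", trait,
           level = "WARN")
  }
  as_records(data.frame(animal_id = df$animal_id, breed = df$breed,
                        lactation_number = df$lactation_number,
                        hys = df$hys, yield = y[!drop],
                        trait = rep(trait, length.out = nrow(df)),
                        stringsAsFactors = FALSE))
}

#' @rdname read_phenotypes
#' @param records A `lactation_records` table.
#' @export
write_phenotypes <- function(records, path) {
  stopifnot(inherits(records, "lactation_records"))
  trait <- unique(records$trait)
  if (length(trait) != 1L) stop("write_phenotypes expects a single trait")
  ycol <- c(MY = "my_305", FY = "fy_305", PY = "py_305")[[trait]]
  out <- data.frame(animal_id = records$animal_id, breed = records$breed,
                    lactation_number = records$lactation_number,
                    hys = records$hys)
  out[[ycol]] <- records$yield
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
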