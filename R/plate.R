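# Coregulator binding-plate container, 96-well indexing and I/O.

WELL_ROWS <- LETTERS[1:8]

#' Convert between 96-well labels and sequential fraction indices
#'
#' Fractions are collected and screened in row-major plate order
#' (A1...A12, B1...B12, ..., H12), so well labels map bijectively onto
#' sequential indices 1-96: `B12 -> 24`, `C4 -> 28`, `D6 -> 42`.
#'
#' @param label Character vector of well labels (`A1`-`H12`).
#' @param index Integer vector of indices (1-96).
#' @return `well_index()`: integer indices; `index_well()`: well labels.
#' @export
#' @examples
#' well_index(c("A1", "B12", "C4", "D6"))
#' index_well(1:4)
well_index <- function(label) {
  label <- toupper(trimws(label))
  m <- regmatches(label, regexec("^([A-H])([0-9]{1,2})$", label))
  out <- vapply(seq_along(label), function(i) {
    parts <- m[[i]]
    if (length(parts) != 3) {
      abort(paste0("unknown well label: '", label[i], "'"))
    }
    col <- as.integer(parts[3])
    if (col < 1 || col > 12) {
      abort(paste0("unknown well label: '", label[i], "'"))
    }
    (match(parts[2], WELL_ROWS) - 1L) * 12L + col
  }, integer(1))
  out
}

#' @rdname well_index
#' @export
index_well <- function(index) {
  index <- as.integer(index)
  if (any(is.na(index) | index < 1 | index > 96)) {
    abort("fraction index out of range 1-96")
  }
  paste0(WELL_ROWS[(index - 1L) %/% 12L + 1L], (index - 1L) %% 12L + 1L)
}

is_well_label <- function(x) {
  grepl("^[A-H](1[0-2]|[1-9])$", toupper(trimws(x)))
}

# Classify condition names: the unstimulated reference is "Apo", the
# glucocorticoid control "Cortisol", fraction conditions are named by their
# well label, and spiked (competition) conditions are "<stimulus>+<motif>".
condition_meta <- function(conditions) {
  conditions <- unique(conditions)
  type <- rep("other", length(conditions))
  fraction_index <- rep(NA_integer_, length(conditions))
  stimulus <- rep(NA_character_, length(conditions))
  spiked_motif <- rep(NA_character_, length(conditions))
  for (i in seq_along(conditions)) {
    cn <- conditions[i]
    if (tolower(cn) == "apo") {
      type[i] <- "apo"
    } else if (tolower(cn) %in% c("cortisol", "cort")) {
      type[i] <- "cortisol"
    } else if (is_well_label(cn)) {
      type[i] <- "fraction"
      fraction_index[i] <- well_index(cn)
    } else if (grepl("+", cn, fixed = TRUE)) {
      parts <- strsplit(cn, "+", fixed = TRUE)[[1]]
      type[i] <- "spiked"
      stimulus[i] <- parts[1]
      spiked_motif[i] <- parts[2]
    }
  }
  tibble(condition = conditions, type = type,
         fraction_index = fraction_index,
         stimulus = stimulus, spiked_motif = spiked_motif)
}

#' Construct a validated binding plate
#'
#' One plate holds fluorescence intensities for the binding of a nuclear
#' receptor to a library of immobilized coregulator motifs under a set of
#' conditions: the unstimulated receptor (`Apo`, mandatory and unique), an
#' optional glucocorticoid control (`Cortisol`), sequential plant-fraction
#' wells named by their 96-well label, and optional spiked competition
#' conditions named `<stimulus>+<motif>`.
#'
#' @param data Long-format data frame with columns `motif`, `condition`,
#'   `replicate`, `value` (and optionally `plant_id`, `well`).
#' @param plant_id Plant/extract identifier (defaults to the `plant_id`
#'   column when present).
#' @return Object of class `binding_plate`: list with `plant_id`, `data`
#'   (tibble), `motifs` (ordered character), `conditions` (metadata tibble
#'   with `type` and `fraction_index`).
#' @export
binding_plate <- function(data, plant_id = NULL) {
  data <- as_tibble(data)
  required <- c("motif", "condition", "replicate", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("plate data lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (is.null(plant_id)) {
    plant_id <- if ("plant_id" %in% names(data)) data$plant_id[1] else "plate"
  }
  data$motif <- as.character(data$motif)
  data$condition <- as.character(data$condition)
  data$replicate <- as.integer(data$replicate)
  data$value <- as.numeric(data$value)
  if (any(is.na(data$value)) || any(data$value < 0)) {
    bad <- which(is.na(data$value) | data$value < 0)[1]
    abort(paste0("negative or missing fluorescence value in row ", bad))
  }
  meta <- condition_meta(data$condition)
  if (sum(meta$type == "apo") != 1) {
    abort("plate must contain exactly one Apo condition")
  }
  data$plant_id <- plant_id
  structure(
    list(plant_id = plant_id,
         data = data[, c("plant_id", "motif", "condition", "replicate",
                         "value")],
         motifs = unique(data$motif),
         conditions = meta),
    class = "binding_plate"
  )
}

#' @export
print.binding_plate <- function(x, ...) {
  tab <- table(x$conditions$type)
  cat("<binding_plate '", x$plant_id, "'> ", length(x$motifs), " motifs; ",
      paste(names(tab), as.integer(tab), sep = ": ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read or write a binding plate (long CSV or JSON)
#'
#' CSV columns: `plant_id`, `motif`, `condition`, `well`, `replicate`,
#' `value`; the JSON form is `{"plant_id": ..., "records": [...]}` with the
#' same fields per record.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return [read_plate()]: a validated [binding_plate()];
#'   [write_plate()]: `path`, invisibly.
#' @export
read_plate <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("plate file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(
      plant_id = "c", motif = "c", condition = "c", well = "c",
      replicate = "i", value = "d"))
    binding_plate(raw)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    binding_plate(as_tibble(obj$records), plant_id = obj$plant_id)
  }
}

#' @rdname read_plate
#' @param x A `binding_plate`.
#' @export
write_plate <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "binding_plate"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  out <- x$data
  meta <- x$conditions
  ctype <- meta$type[match(out$condition, meta$condition)]
  out$well <- ifelse(ctype == "fraction", out$condition, NA_character_)
  out <- out[, c("plant_id", "motif", "condition", "well", "replicate",
                 "value")]
  if (format == "csv") {
    readr::write_csv(out, path)
  } else {
    jsonlite::write_json(list(plant_id = x$plant_id, records = out), path,
                         auto_unbox = TRUE, dataframe = "rows", digits = NA)
  }
  invisible(path)
}

#' Test two plates for equality of their measurements
#'
#' @param a,b `binding_plate` objects.
#' @param tol Numeric tolerance on fluorescence values.
#' @return `TRUE` or `FALSE`.
#' @export
plate_equal <- function(a, b, tol = 1e-8) {
  stopifnot(inherits(a, "binding_plate"), inherits(b, "binding_plate"))
  key <- function(p) {
    d <- p$data[order(p$data$motif, p$data$condition, p$data$replicate), ]
    d
  }
  da <- key(a); db <- key(b)
  identical(a$plant_id, b$plant_id) &&
    nrow(da) == nrow(db) &&
    identical(da$motif, db$motif) &&
    identical(da$condition, db$condition) &&
    identical(da$replicate, db$replicate) &&
    max(abs(da$value - db$value)) <= tol
}
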