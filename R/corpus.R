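#' @importFrom rlang .data abort warn %||% :=
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n rename
#' @importFrom tibble tibble as_tibble
NULL

SUBSET_NAMES <- c(
  "all_terms", "arthritis_main_orbit", "arthritis_main",
  "skin", "arthritis_and_skin"
)

#' Normalize an indication term or drug name
#'
#' Folds case and collapses internal/leading/trailing whitespace so that term
#' matching between recipes and search-term tables is exact string equality on
#' the normalized form. No fuzzy matching is performed.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_term(c("  Hexi  Feng ", "FENG BI"))
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a validated recipe corpus
#'
#' A corpus is a collection of historical medical recipes, each carrying a
#' non-empty set of indication terms and a non-empty set of ingredient
#' (botanical drug) identifiers. Indication and ingredient vocabularies are
#' derived from the recipes.
#'
#' @param recipes A data frame with columns `recipe_id`, `title`, `source_id`
#'   (character) and list-columns `indications` and `ingredients` (character
#'   vectors). `title` and `source_id` may be omitted and default to `""`.
#' @return An object of class `corpus`: a list with elements `recipes`
#'   (tibble), `ingredient_vocabulary` and `term_vocabulary` (character).
#' @export
corpus <- function(recipes) {
  recipes <- as_tibble(recipes)
  required <- c("recipe_id", "indications", "ingredients")
  missing_cols <- setdiff(required, names(recipes))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus recipes lack column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(recipes) == 0) abort("empty corpus: no recipes")
  if (!"title" %in% names(recipes)) recipes$title <- ""
  if (!"source_id" %in% names(recipes)) recipes$source_id <- ""
  recipes$recipe_id <- as.character(recipes$recipe_id)

  dup <- recipes$recipe_id[duplicated(recipes$recipe_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated recipe_id: ", paste(unique(dup), collapse = ", ")))
  }
  recipes$indications <- lapply(recipes$indications,
                                function(x) unique(normalize_term(x)))
  recipes$ingredients <- lapply(recipes$ingredients,
                                function(x) unique(normalize_term(x)))
  n_ind <- lengths(recipes$indications)
  n_ing <- lengths(recipes$ingredients)
  if (any(n_ind == 0)) {
    abort(paste0("recipe without indications: ",
                 paste(recipes$recipe_id[n_ind == 0][1:min(3, sum(n_ind == 0))],
                       collapse = ", ")))
  }
  if (any(n_ing == 0)) {
    abort(paste0("recipe without ingredients: ",
                 paste(recipes$recipe_id[n_ing == 0][1:min(3, sum(n_ing == 0))],
                       collapse = ", ")))
  }
  recipes <- recipes[, c("recipe_id", "title", "source_id",
                         "indications", "ingredients",
                         setdiff(names(recipes),
                                 c("recipe_id", "title", "source_id",
                                   "indications", "ingredients")))]
  structure(
    list(
      recipes = recipes,
      ingredient_vocabulary = sort(unique(unlist(recipes$ingredients))),
      term_vocabulary = sort(unique(unlist(recipes$indications)))
    ),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  cat("<corpus>", nrow(x$recipes), "recipes |",
      length(x$term_vocabulary), "indication terms |",
      length(x$ingredient_vocabulary), "ingredients\n")
  invisible(x)
}

#' @export
format.corpus <- function(x, ...) {
  paste0("<corpus: ", nrow(x$recipes), " recipes>")
}

#' Test two corpora for equality
#'
#' Order-insensitive within the indication and ingredient sets of each recipe,
#' order-sensitive in recipe order (readers preserve file order).
#'
#' @param a,b `corpus` objects.
#' @return `TRUE` or `FALSE`.
#' @export
corpus_equal <- function(a, b) {
  stopifnot(inherits(a, "corpus"), inherits(b, "corpus"))
  if (nrow(a$recipes) != nrow(b$recipes)) return(FALSE)
  norm <- function(co) {
    r <- co$recipes[order(co$recipes$recipe_id),
                    c("recipe_id", "title", "source_id")]
    r$indications <- lapply(co$recipes$indications[order(co$recipes$recipe_id)], sort)
    r$ingredients <- lapply(co$recipes$ingredients[order(co$recipes$recipe_id)], sort)
    r
  }
  isTRUE(all.equal(norm(a), norm(b), check.attributes = FALSE))
}

# ---- I/O ---------------------------------------------------------------

#' Read a recipe corpus from CSV or JSON
#'
#' CSV files are UTF-8 with a header row and `|`-delimited list cells for the
#' `indications` and `ingredients` columns; JSON files are an array of recipe
#' objects with native array fields.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A validated [corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("corpus file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    for (col in c("recipe_id", "indications", "ingredients")) {
      if (!col %in% names(raw)) {
        abort(paste0("corpus CSV lacks required column '", col, "'"))
      }
    }
    bad <- which(is.na(raw$recipe_id) | is.na(raw$indications) |
                   is.na(raw$ingredients))
    if (length(bad) > 0) {
      abort(paste0("corpus CSV row ", bad[1],
                   ": missing recipe_id/indications/ingredients"))
    }
    split_cell <- function(x) strsplit(x, "|", fixed = TRUE)
    raw$indications <- split_cell(raw$indications)
    raw$ingredients <- split_cell(raw$ingredients)
    corpus(raw)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (length(recs) == 0) abort("empty corpus: no recipes")
    rows <- purrr::map(recs, function(r) {
      for (col in c("recipe_id", "indications", "ingredients")) {
        if (is.null(r[[col]])) {
          abort(paste0("corpus JSON record '",
                       r$recipe_id %||% "<no id>",
                       "' lacks field '", col, "'"))
        }
      }
      tibble(
        recipe_id = as.character(r$recipe_id),
        title = as.character(r$title %||% ""),
        source_id = as.character(r$source_id %||% ""),
        indications = list(unlist(r$indications)),
        ingredients = list(unlist(r$ingredients))
      )
    })
    corpus(bind_rows(rows))
  }
}

#' Write a recipe corpus to CSV or JSON
#'
#' @inheritParams read_corpus
#' @param x A `corpus`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("auto", "csv", "json")) {
  stopifnot(inherits(x, "corpus"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    out <- x$recipes[, c("recipe_id", "title", "source_id")]
    out$indications <- vapply(x$recipes$indications, paste, "", collapse = "|")
    out$ingredients <- vapply(x$recipes$ingredients, paste, "", collapse = "|")
    readr::write_csv(out, path)
  } else {
    recs <- purrr::pmap(
      list(x$recipes$recipe_id, x$recipes$title, x$recipes$source_id,
           x$recipes$indications, x$recipes$ingredients),
      function(id, title, src, ind, ing) {
        list(recipe_id = id, title = title, source_id = src,
             indications = as.list(ind), ingredients = as.list(ing))
      }
    )
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = FALSE)
  }
  invisible(path)
}

#' Construct a validated search-term table
#'
#' Search terms are historical indication names used to select recipes. Each
#' carries a category (`arthritis` or `skin`) and, for arthritis terms, a
#' granularity: `main` for terms clearly identifiable as arthritis, `orbit`
#' for related but less specific musculoskeletal complaints. Skin terms carry
#' granularity `none`.
#'
#' @param terms Data frame with columns `term`, `category`, `granularity`
#'   and optionally `transliteration`.
#' @return A tibble of class `search_terms` with normalized `term`.
#' @export
search_terms <- function(terms) {
  terms <- as_tibble(terms)
  for (col in c("term", "category")) {
    if (!col %in% names(terms)) {
      abort(paste0("search-term table lacks column '", col, "'"))
    }
  }
  if (!"granularity" %in% names(terms)) terms$granularity <- NA_character_
  if (!"transliteration" %in% names(terms)) terms$transliteration <- ""
  terms$term <- normalize_term(terms$term)
  terms$category <- tolower(trimws(terms$category))
  terms$granularity <- tolower(trimws(terms$granularity))
  terms$granularity[is.na(terms$granularity) | terms$granularity == ""] <- "none"
  bad_cat <- !terms$category %in% c("arthritis", "skin")
  if (any(bad_cat)) {
    abort(paste0("invalid search-term category in row ", which(bad_cat)[1],
                 ": '", terms$category[bad_cat][1], "'"))
  }
  bad_gran <- (terms$category == "arthritis" &
                 !terms$granularity %in% c("main", "orbit")) |
    (terms$category == "skin" & terms$granularity != "none")
  if (any(bad_gran)) {
    abort(paste0("invalid category/granularity combination in row ",
                 which(bad_gran)[1], ": ", terms$category[bad_gran][1],
                 "/", terms$granularity[bad_gran][1]))
  }
  if (anyDuplicated(terms$term)) {
    abort("duplicated search terms after normalization")
  }
  structure(
    terms[, c("term", "transliteration", "category", "granularity")],
    class = c("search_terms", class(tibble())))
}

#' Read a search-term table from CSV
#'
#' Expects columns `term`, `transliteration`, `category`, `granularity`.
#'
#' @param path File path.
#' @return A [search_terms()] tibble.
#' @export
read_search_terms <- function(path) {
  if (!file.exists(path)) abort(paste0("search-term file not found: ", path))
  search_terms(readr::read_csv(path, col_types = readr::cols(.default = "c")))
}

#' Read a drug annotation table from CSV
#'
#' Literature-derived classification of candidate drugs, columns `drug` and
#' `classification` (one of `specific`, `unspecific`, `toxic`). Pass-through
#' input for [rank_matrix()]; never computed here.
#'
#' @param path File path.
#' @return Tibble with normalized `drug` and `classification`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  ann <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  for (col in c("drug", "classification")) {
    if (!col %in% names(ann)) {
      abort(paste0("annotation table lacks column '", col, "'"))
    }
  }
  ann$drug <- normalize_term(ann$drug)
  ann$classification <- tolower(trimws(ann$classification))
  bad <- !ann$classification %in% c("specific", "unspecific", "toxic")
  if (any(bad)) {
    abort(paste0("invalid classification '", ann$classification[bad][1], "'"))
  }
  as_tibble(ann[, c("drug", "classification")])
}

# ---- selection ----------------------------------------------------------

new_selection <- function(name, recipe_ids, terms_used, attribution = NULL) {
  structure(
    list(name = name, recipe_ids = recipe_ids, terms_used = terms_used,
         attribution = attribution),
    class = "dataset_selection"
  )
}

#' @export
print.dataset_selection <- function(x, ...) {
  cat("<dataset_selection '", x$name, "'> ", length(x$recipe_ids),
      " recipes, ", nrow(x$terms_used), " terms\n", sep = "")
  invisible(x)
}

#' Select the recipes linked to a set of search terms
#'
#' A recipe is selected when its indication set intersects the term set; each
#' recipe appears once no matter how many terms it matches. Matching is exact
#' string equality on normalized terms.
#'
#' @param corpus A [corpus()].
#' @param terms A [search_terms()] tibble or a character vector of terms.
#' @param name Selection name.
#' @return A `dataset_selection`: list with `name`, `recipe_ids` (character,
#'   in corpus order), `terms_used` (tibble).
#' @export
link_recipes <- function(corpus, terms, name = "custom") {
  stopifnot(inherits(corpus, "corpus"))
  if (is.character(terms)) {
    terms <- search_terms(tibble(term = terms, category = "arthritis",
                                 granularity = "main"))
  }
  if (nrow(terms) == 0) abort("term set is empty")
  term_set <- unique(terms$term)
  hit <- vapply(corpus$recipes$indications,
                function(ind) any(ind %in% term_set), logical(1))
  if (!any(hit)) {
    warn(paste0("no recipe matches any of the ", length(term_set),
                " search terms; selection '", name, "' is empty"))
  }
  new_selection(name, corpus$recipes$recipe_id[hit], terms)
}

#' Build the joint dataset and its four subsets
#'
#' Constructs the five standard selections from a corpus and a search-term
#' table:
#' \describe{
#'   \item{all_terms}{recipes linked to any search term (the joint dataset)}
#'   \item{arthritis_main_orbit}{recipes linked to any arthritis term, each
#'     attributed to `Main` if it is linked to at least one main-granularity
#'     term, else `Orbit` (a partition)}
#'   \item{arthritis_main}{recipes linked to a main-granularity arthritis term}
#'   \item{skin}{recipes linked to a skin term}
#'   \item{arthritis_and_skin}{recipes linked to both an arthritis and a skin
#'     term}
#' }
#'
#' @param corpus A [corpus()].
#' @param terms A [search_terms()] tibble covering both categories.
#' @return Named list of `dataset_selection` objects; the
#'   `arthritis_main_orbit` element carries an `attribution` tibble
#'   (`recipe_id`, `group` in `Main`/`Orbit`).
#' @export
build_subsets <- function(corpus, terms) {
  stopifnot(inherits(corpus, "corpus"))
  if (!inherits(terms, "search_terms")) terms <- search_terms(terms)

  arth <- terms[terms$category == "arthritis", ]
  main <- arth[arth$granularity == "main", ]
  skin <- terms[terms$category == "skin", ]

  all_sel <- link_recipes(corpus, terms, "all_terms")
  arth_sel <- if (nrow(arth) > 0) {
    link_recipes(corpus, arth, "arthritis_main_orbit")
  } else new_selection("arthritis_main_orbit", character(0), arth)
  main_sel <- if (nrow(main) > 0) {
    link_recipes(corpus, main, "arthritis_main")
  } else new_selection("arthritis_main", character(0), main)
  skin_sel <- if (nrow(skin) > 0) {
    link_recipes(corpus, skin, "skin")
  } else new_selection("skin", character(0), skin)
  both_ids <- intersect(skin_sel$recipe_ids, arth_sel$recipe_ids)
  both_sel <- new_selection("arthritis_and_skin",
                            all_sel$recipe_ids[all_sel$recipe_ids %in% both_ids],
                            terms)

  # Main/Orbit partition of the arthritis selection: any main-granularity
  # link wins, so counts add up to the subset size exactly.
  if (length(arth_sel$recipe_ids) > 0) {
    idx <- match(arth_sel$recipe_ids, corpus$recipes$recipe_id)
    is_main <- vapply(corpus$recipes$indications[idx],
                      function(ind) any(ind %in% main$term), logical(1))
    arth_sel$attribution <- tibble(
      recipe_id = arth_sel$recipe_ids,
      group = ifelse(is_main, "Main", "Orbit")
    )
  } else {
    arth_sel$attribution <- tibble(recipe_id = character(0),
                                   group = character(0))
  }

  out <- list(all_terms = all_sel,
              arthritis_main_orbit = arth_sel,
              arthritis_main = main_sel,
              skin = skin_sel,
              arthritis_and_skin = both_sel)
  stopifnot(
    all(out$arthritis_and_skin$recipe_ids %in% out$skin$recipe_ids),
    all(out$arthritis_and_skin$recipe_ids %in%
          out$arthritis_main_orbit$recipe_ids),
    all(out$arthritis_main$recipe_ids %in%
          out$arthritis_main_orbit$recipe_ids),
    all(unlist(lapply(out[-1], `[[`, "recipe_ids")) %in%
          out$all_terms$recipe_ids)
  )
  out
}

#' Summarise a list of selections as a tibble
#'
#' @param subsets Result of [build_subsets()].
#' @return Tibble with one row per subset: `subset`, `n_recipes`, and the
#'   Main/Orbit split for the arthritis subset.
#' @export
subset_sizes <- function(subsets) {
  tibble(
    subset = names(subsets),
    n_recipes = vapply(subsets, function(s) length(s$recipe_ids), integer(1)),
    n_main = vapply(subsets, function(s) {
      if (is.null(s$attribution)) NA_integer_ else
        sum(s$attribution$group == "Main")
    }, integer(1)),
    n_orbit = vapply(subsets, function(s) {
      if (is.null(s$attribution)) NA_integer_ else
        sum(s$attribution$group == "Orbit")
    }, integer(1))
  )
}
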