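#' Normalize free text into a term sequence
#'
#' Lowercases, strips punctuation and splits on whitespace. The characters
#' `+` and `-` are kept inside tokens so that chemical notations such as
#' `"K+"` or `"Ca2+"` survive as single terms. Normalization is idempotent:
#' applying it to an already-normalized string returns the same tokens.
#'
#' @param text A character scalar (may be empty or `NA`).
#' @return A character vector of terms; `character(0)` for empty input.
#' @examples
#' normalize_terms("Extracellular Space")
#' normalize_terms("concentration of K+ in extracellular space")
#' @export
normalize_terms <- function(text) {
  if (length(text) == 0L || is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(text)
  x <- gsub("[^a-z0-9+-]+", " ", x)
  tokens <- strsplit(trimws(x), "[ ]+")[[1]]
  # drop tokens that carry no alphanumeric content (bare dashes etc.)
  tokens[grepl("[a-z0-9]", tokens)]
}

# Function words at which the built-in chunker splits noun-phrase groups.
.function_words <- c(
  "of", "in", "on", "at", "to", "for", "with", "within", "into", "across",
  "from", "by", "the", "a", "an", "and", "or", "between", "through", "over",
  "under", "per", "via", "as", "is", "are"
)

#' Heuristic dependency levels for a term sequence
#'
#' Deterministic stand-in for a dependency parser. Terms are grouped at
#' function words (prepositions, determiners); the final content term of the
#' first group is the root (level 1), the head of every later group attaches
#' to the root (level 2), non-head content terms chain onto their group head
#' (depth + 1 per step), and each function word attaches to the head of the
#' group that follows it. Levels are node depth + 1, so exactly one term has
#' level 1.
#'
#' @param terms A normalized term sequence (see [normalize_terms()]).
#' @return An integer vector of dependency levels, one per term, all `>= 1`.
#' @examples
#' builtin_dependency_levels(c("concentration", "of", "potassium"))
#' @export
builtin_dependency_levels <- function(terms) {
  n <- length(terms)
  if (n == 0L) return(integer(0))
  is_fun <- terms %in% .function_words
  if (all(is_fun)) {
    # degenerate all-function-word phrase: head-final chain
    return(rev(seq_len(n)))
  }
  levels <- integer(n)
  # contiguous runs of content terms
  runs <- rle(is_fun)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  groups <- Map(function(s, e) s:e, starts[!runs$values], ends[!runs$values])
  heads <- vapply(groups, function(g) g[length(g)], integer(1))
  for (gi in seq_along(groups)) {
    head_level <- if (gi == 1L) 1L else 2L
    g <- groups[[gi]]
    h <- heads[gi]
    levels[g] <- head_level + (h - g)
  }
  # function words attach to the head of the following group (or the
  # preceding one when the phrase ends in a function word)
  for (i in which(is_fun)) {
    nxt <- heads[heads > i]
    anchor <- if (length(nxt)) nxt[1] else heads[length(heads)]
    levels[i] <- levels[anchor] + 1L
  }
  levels
}

#' Built-in deterministic chunker
#'
#' Emulates constituency-parser noun-phrase extraction for prepositional
#' noun-phrase queries. Candidates are: the full sequence; each prefix ending
#' just before a function word; each contiguous content-term group; and each
#' group head alone. Spans are 0-based half-open token offsets.
#'
#' @param terms A normalized term sequence.
#' @return A data.frame with columns `start`, `end` (0-based half-open).
#' @export
builtin_chunk <- function(terms) {
  n <- length(terms)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  is_fun <- terms %in% .function_words
  spans <- list(c(0L, n))
  # prefixes ending just before each function word with content before it
  for (i in which(is_fun)) {
    if (i > 1L && any(!is_fun[seq_len(i - 1L)])) {
      spans[[length(spans) + 1L]] <- c(0L, i - 1L)
    }
  }
  if (any(!is_fun)) {
    runs <- rle(is_fun)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(!runs$values)) {
      s <- starts[k]; e <- ends[k]
      spans[[length(spans) + 1L]] <- c(s - 1L, e)        # the group
      spans[[length(spans) + 1L]] <- c(e - 1L, e)        # its head
    }
  }
  m <- unique(do.call(rbind, spans))
  m <- m[order(m[, 1], -(m[, 2] - m[, 1])), , drop = FALSE]
  data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Default lexicon for the built-in named-entity recognizer
#'
#' A small deterministic gazetteer keyed by space-joined normalized phrases,
#' mapping to coarse biomedical entity types. It covers the vocabulary used
#' by the synthetic fixture generators so NER-driven code paths are testable
#' without external models.
#'
#' @return A named character vector: phrase -> entity type.
#' @export
builtin_ner_lexicon <- function() {
  c(
    "potassium" = "SIMPLE_CHEMICAL",
    "sodium" = "SIMPLE_CHEMICAL",
    "calcium" = "SIMPLE_CHEMICAL",
    "chloride" = "SIMPLE_CHEMICAL",
    "glucose" = "SIMPLE_CHEMICAL",
    "bicarbonate" = "SIMPLE_CHEMICAL",
    "k+" = "SIMPLE_CHEMICAL",
    "na+" = "SIMPLE_CHEMICAL",
    "extracellular space" = "ANATOMY",
    "intracellular space" = "ANATOMY",
    "cytosol" = "ANATOMY",
    "plasma membrane" = "ANATOMY",
    "apical plasma membrane" = "ANATOMY",
    "basolateral plasma membrane" = "ANATOMY",
    "cardiac myocyte" = "CELL",
    "epithelial cell" = "CELL"
  )
}

.builtin_ner <- function(terms, lexicon) {
  n <- length(terms)
  out <- list()
  i <- 1L
  max_len <- max(c(1L, lengths(strsplit(names(lexicon), " ", fixed = TRUE))))
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      key <- paste(terms[i:(i + len - 1L)], collapse = " ")
      if (!is.na(lexicon[key])) {
        hit <- list(start = i - 1L, end = i + len - 1L, type = unname(lexicon[key]))
        break
      }
    }
    if (is.null(hit)) {
      i <- i + 1L
    } else {
      out[[length(out) + 1L]] <- hit
      i <- i + (hit$end - hit$start)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0), type = character(0)))
  }
  data.frame(
    start = vapply(out, `[[`, integer(1), "start"),
    end = vapply(out, `[[`, integer(1), "end"),
    type = vapply(out, `[[`, character(1), "type")
  )
}

#' Construct the built-in parser adapter
#'
#' A parser adapter bundles three callbacks operating on normalized term
#' sequences: `chunk(terms)` returning candidate spans, `deps(terms)`
#' returning per-term dependency levels, and `ner(terms)` returning entity
#' spans with types (or `NULL` when the backend has no NER). External
#' backends (constituency parsers, biomedical NER models) can be plugged in
#' with [register_parser_adapter()]; the built-in adapter is deterministic
#' and dependency-free.
#'
#' @param lexicon Named character vector used by the mock NER; see
#'   [builtin_ner_lexicon()].
#' @return An object of class `parser_adapter`.
#' @export
builtin_parser <- function(lexicon = builtin_ner_lexicon()) {
  structure(
    list(
      name = "builtin",
      chunk = builtin_chunk,
      deps = builtin_dependency_levels,
      ner = function(terms) .builtin_ner(terms, lexicon)
    ),
    class = "parser_adapter"
  )
}

.adapter_registry <- new.env(parent = emptyenv())

#' Register or fetch a parser adapter by name
#'
#' @param name Adapter name as used in `AnnotatorConfig$parser`.
#' @param adapter A `parser_adapter` object.
#' @return `register_parser_adapter` returns the adapter invisibly;
#'   `get_parser_adapter` returns the registered adapter, or the built-in
#'   adapter for the names `"builtin"`, `"builtin-ner"` and `"builtin-xner"`.
#' @export
register_parser_adapter <- function(name, adapter) {
  stopifnot(is.character(name), inherits(adapter, "parser_adapter"))
  assign(name, adapter, envir = .adapter_registry)
  invisible(adapter)
}

#' @rdname register_parser_adapter
#' @export
get_parser_adapter <- function(name) {
  if (exists(name, envir = .adapter_registry, inherits = FALSE)) {
    return(get(name, envir = .adapter_registry, inherits = FALSE))
  }
  if (name %in% c("builtin", "builtin-ner", "builtin-xner")) {
    return(builtin_parser())
  }
  stop("unknown parser adapter: ", name, call. = FALSE)
}
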