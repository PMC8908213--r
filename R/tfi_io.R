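#' Save and load the Text Feature Index
#'
#' Like [save_rgi()], the TFI is written as JSON into a content-addressed
#' file `tfi-<md5>.json`. Feature records are stored post-WPL, so loading
#' never re-applies the preferred-label distribution; the inverted postings
#' are rebuilt from the stored records.
#'
#' @param tfi A [build_tfi()] index.
#' @param dir Output directory (created if needed).
#' @param path Saved index file or directory.
#' @return `save_tfi` returns the file path; `load_tfi` the restored `tfi`.
#' @export
save_tfi <- function(tfi, dir) {
  ser_record <- function(r) {
    list(kind = r$kind, terms = r$terms, dl = r$dl, length = r$length)
  }
  ser_class <- function(cl) {
    list(
      iri = cl$iri,
      ontology_id = cl$ontology_id,
      preferred_label = ser_record(cl$preferred_label),
      synonyms = lapply(cl$synonyms, ser_record),
      definition = if (is.null(cl$definition)) NULL else ser_record(cl$definition),
      parent_labels = lapply(cl$parent_labels, ser_record)
    )
  }
  payload <- list(
    format = "tfi/1",
    classes = lapply(.env_to_list(tfi$classes), ser_class),
    desc = .env_to_list(tfi$desc),
    config = unclass(tfi$config)
  )
  .save_content_addressed(payload, dir, "tfi")
}

#' @rdname save_tfi
#' @export
load_tfi <- function(path) {
  payload <- .load_content_addressed(path, "tfi")
  de_record <- function(r) {
    structure(
      list(kind = r$kind, terms = as.character(unlist(r$terms)),
           dl = as.integer(unlist(r$dl)), length = as.integer(r$length)),
      class = "feature_record"
    )
  }
  de_class <- function(cl) {
    structure(
      list(
        iri = cl$iri,
        ontology_id = cl$ontology_id,
        preferred_label = de_record(cl$preferred_label),
        synonyms = lapply(cl$synonyms, de_record),
        definition = if (is.null(cl$definition)) NULL else de_record(cl$definition),
        parent_labels = lapply(cl$parent_labels, de_record)
      ),
      class = "ontology_class"
    )
  }
  classes <- lapply(payload$classes, de_class)
  class_store <- new.env(parent = emptyenv())
  for (cl in classes) assign(cl$iri, cl, envir = class_store)
  desc_store <- new.env(parent = emptyenv())
  for (iri in names(payload$desc)) {
    d <- payload$desc[[iri]]
    assign(iri, list(terms = as.character(unlist(d$terms)),
                     te_a = as.integer(d$te_a), te_o = as.integer(d$te_o)),
           envir = desc_store)
  }
  cfg_vals <- payload$config
  cfg_vals$stopwords <- as.character(unlist(cfg_vals$stopwords))
  config <- do.call(annotator_config, cfg_vals)
  postings <- .rebuild_postings(class_store, desc_store, config)
  structure(
    list(postings = postings, classes = class_store, desc = desc_store,
         config = config),
    class = "tfi"
  )
}

# inverted postings from already-built class and description stores
.rebuild_postings <- function(class_store, desc_store, config) {
  postings <- new.env(parent = emptyenv())
  add <- function(t, entry) {
    cur <- if (exists(t, envir = postings, inherits = FALSE)) {
      get(t, envir = postings, inherits = FALSE)
    }
    assign(t, rbind(cur, entry), envir = postings)
  }
  for (iri in ls(class_store)) {
    cl <- get(iri, envir = class_store, inherits = FALSE)
    for (rec in .class_features(cl)) {
      for (t in setdiff(unique(rec$terms), config$stopwords)) {
        add(t, data.frame(class = cl$iri, kind = rec$kind,
                          dl = min(rec$dl[rec$terms == t]), flen = rec$length,
                          stringsAsFactors = FALSE))
      }
    }
  }
  for (iri in ls(desc_store)) {
    d <- get(iri, envir = desc_store, inherits = FALSE)
    for (t in unique(d$terms)) {
      add(t, data.frame(class = iri, kind = "description", dl = NA_integer_,
                        flen = NA_integer_, stringsAsFactors = FALSE))
    }
  }
  for (t in ls(postings)) {
    df <- unique(get(t, envir = postings, inherits = FALSE))
    df <- df[order(df$class, df$kind, df$dl, df$flen), , drop = FALSE]
    rownames(df) <- NULL
    assign(t, df, envir = postings)
  }
  postings
}
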