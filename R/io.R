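# The JSON domain-spec dialect: schema-checked reader and writer with
# round-trip identity. Integer windows are materialized into explicit label
# sets at read time, so the core never sees integers.

SPEC_FORMAT_VERSION <- 1L

schema_fail <- function(pointer, msg) {
  cs_stop("catsys_schema_error", sprintf("%s: %s", pointer, msg),
          pointer = pointer)
}

#' Write a domain spec to the JSON dialect
#'
#' The document carries `format_version`, `name`, `style`, `sets` (key to
#' label array), `maps` (key to `{dom, cod, assign}` with set keys as
#' references), `roles`, and for the characteristic style a `relation` pair
#' list. Sets are always written explicitly (windows are a read-time
#' convenience), so `read_domain_spec(write_domain_spec(s))` returns an
#' equal spec.
#'
#' @param spec a [domain_spec()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_domain_spec <- function(spec, path) {
  cs_assert(inherits(spec, "domain_spec"), "catsys_malformed_spec",
            "write_domain_spec expects a domain_spec")
  set_key_of <- function(s) {
    for (k in names(spec$sets)) if (fset_equal(spec$sets[[k]], s)) return(k)
    cs_stop("catsys_referential_error",
            sprintf("map endpoint %s matches no declared set", format(s)))
  }
  doc <- list(
    format_version = SPEC_FORMAT_VERSION,
    name = spec$name,
    style = spec$style,
    sets = lapply(spec$sets, function(s) s$elements),
    maps = lapply(spec$maps, function(m) {
      list(dom = set_key_of(m$dom), cod = set_key_of(m$cod),
           assign = as.list(m$assignment))
    }),
    roles = as.list(spec$roles)
  )
  if (!is.null(spec$relation)) {
    doc$relation <- lapply(spec$relation, function(pr) as.list(unname(pr)))
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a domain spec from the JSON dialect
#'
#' Validates the document shape first (reporting the JSON-pointer-style
#' location of the first violation), then referential integrity (maps must
#' reference declared sets, assignments must target declared elements —
#' these raise `catsys_referential_error`), and finally the style rules of
#' [domain_spec()]. An optional `windows` object (`{"setkey": [lo, hi]}`)
#' declares a set as an inclusive integer window, materialized into labels
#' on read.
#'
#' @param path file path of a spec document.
#' @return A [domain_spec()].
#' @export
read_domain_spec <- function(path) {
  cs_assert(file.exists(path), "catsys_schema_error",
            sprintf("no such file: %s", path))
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.list(doc)) schema_fail("/", "document must be a JSON object")
  for (field in c("name", "style", "sets")) {
    if (is.null(doc[[field]])) schema_fail(paste0("/", field), "missing required field")
  }
  if (!is.character(doc$name) && !is.character(unlist(doc$name)))
    schema_fail("/name", "must be a string")
  style <- unlist(doc$style)
  if (!is.character(style) || length(style) != 1L)
    schema_fail("/style", "must be a string")
  if (!style %in% DOMAIN_STYLES)
    schema_fail("/style", sprintf("unknown style '%s'", style))
  if (style == "characteristic" && is.null(doc$relation))
    schema_fail("/relation", "characteristic style requires a relation pair list")

  windows <- doc$windows %||% list()
  sets <- list()
  for (k in names(doc$sets)) {
    v <- doc$sets[[k]]
    if (!is.list(v) && !is.character(v))
      schema_fail(paste0("/sets/", k), "must be an array of labels")
    sets[[k]] <- fset(unlist(v) %||% character(0), name = k)
  }
  for (k in names(windows)) {
    w <- unlist(windows[[k]])
    if (length(w) != 2L || anyNA(suppressWarnings(as.integer(w))))
      schema_fail(paste0("/windows/", k), "must be a [lo, hi] integer pair")
    sets[[k]] <- fset(as.character(seq.int(as.integer(w[1]), as.integer(w[2]))),
                      name = k)
  }

  maps <- list()
  for (k in names(doc$maps %||% list())) {
    m <- doc$maps[[k]]
    ptr <- paste0("/maps/", k)
    for (field in c("dom", "cod", "assign")) {
      if (is.null(m[[field]])) schema_fail(paste0(ptr, "/", field), "missing field")
    }
    dk <- unlist(m$dom); ck <- unlist(m$cod)
    if (!dk %in% names(sets))
      cs_stop("catsys_referential_error",
              sprintf("%s/dom: references undeclared set '%s'", ptr, dk))
    if (!ck %in% names(sets))
      cs_stop("catsys_referential_error",
              sprintf("%s/cod: references undeclared set '%s'", ptr, ck))
    asg <- unlist(m$assign)
    bad <- setdiff(unname(asg), sets[[ck]]$elements)
    if (length(bad))
      cs_stop("catsys_referential_error",
              sprintf("%s/assign: target(s) not declared in set '%s': %s",
                      ptr, ck, paste(bad, collapse = ", ")))
    missing <- setdiff(sets[[dk]]$elements, names(asg))
    if (length(missing))
      cs_stop("catsys_referential_error",
              sprintf("%s/assign: unassigned element(s) of set '%s': %s",
                      ptr, dk, paste(missing, collapse = ", ")))
    maps[[k]] <- fmap(sets[[dk]], sets[[ck]], asg, name = k)
  }

  roles <- unlist(doc$roles %||% list())
  relation <- NULL
  if (!is.null(doc$relation)) {
    relation <- lapply(seq_along(doc$relation), function(i) {
      pr <- unlist(doc$relation[[i]])
      if (length(pr) != 2L)
        schema_fail(sprintf("/relation/%d", i - 1L), "must be a pair")
      as.character(pr)
    })
  }
  domain_spec(unlist(doc$name), style, sets = sets, maps = maps,
              roles = roles, relation = relation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two domain specs for structural equality
#'
#' Element collections, assignments, roles, relation and style must all
#' agree; display names of inner sets are ignored.
#'
#' @param a,b [domain_spec()] objects.
#' @return Logical.
#' @export
domain_spec_equal <- function(a, b) {
  if (!identical(a$style, b$style) || !identical(a$name, b$name)) return(FALSE)
  if (!setequal(names(a$sets), names(b$sets))) return(FALSE)
  for (k in names(a$sets)) if (!fset_equal(a$sets[[k]], b$sets[[k]])) return(FALSE)
  if (!setequal(names(a$maps), names(b$maps))) return(FALSE)
  for (k in names(a$maps)) if (!fmap_equal(a$maps[[k]], b$maps[[k]])) return(FALSE)
  if (!identical(a$roles[canon_sort(names(a$roles))],
                 b$roles[canon_sort(names(b$roles))])) return(FALSE)
  norm_rel <- function(r) if (is.null(r)) NULL else
    canon_sort(vapply(r, function(p) paste(p, collapse = "\r"), character(1)))
  identical(norm_rel(a$relation), norm_rel(b$relation))
}
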