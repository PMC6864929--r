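#' Terminology codelists
#'
#' A codelist maps clinical codes to the categories used by the bleeding
#' phenotyping rules. Three code systems are supported: `readlike`
#' (primary-care clinical terms), `icd10` (hospital diagnoses and death
#' causes) and `opcs4` (hospital procedures). Every `bleeding` entry must
#' carry an anatomical `site`; all other entries have no site.
#'
#' ICD-10 and OPCS-4 codes are normalised before matching by removing
#' non-alphanumeric characters (dots in particular) and upper-casing, because
#' hospital extracts mix dotted and undotted forms. Read-like codes are
#' matched verbatim.
#'
#' @name codelist
NULL

.code_systems <- c("readlike", "icd10", "opcs4")

.bleeding_sites <- c("intracranial", "aortic_aneurysm_ruptured",
                     "haemopericardium", "gastrointestinal", "other_site")

.critical_sites <- c("intracranial", "aortic_aneurysm_ruptured",
                     "haemopericardium")

#' Normalise clinical codes for matching
#'
#' @param code character vector of codes.
#' @param system character vector of code systems (`readlike`, `icd10`,
#'   `opcs4`), recycled against `code`.
#' @return Character vector of match keys: ICD-10/OPCS-4 codes are stripped
#'   of non-alphanumeric characters and upper-cased; read-like codes are
#'   returned unchanged.
#' @export
normalise_code <- function(code, system) {
  code <- as.character(code)
  system <- rep_len(as.character(system), length(code))
  out <- code
  hosp <- system %in% c("icd10", "opcs4")
  out[hosp] <- toupper(gsub("[^A-Za-z0-9]", "", code[hosp]))
  out
}

#' Load and validate a codelist
#'
#' Reads a CSV file with header columns `code,system,category,site` into a
#' validated `codelist` object. An empty `site` string means no site.
#'
#' @param path path to a CSV codelist file.
#' @param name short label for the codelist.
#' @param version version string.
#' @return A `codelist` object.
#' @details Validation enforces: known code systems; unique `(code, system)`
#'   pairs (also after normalisation); a non-empty anatomical site on every
#'   `bleeding` row and no site elsewhere. A warning is raised if a
#'   diagnosis system (`readlike`, `icd10`) carries no bleeding entry, since
#'   such a list cannot support bleeding phenotyping for that source.
#' @export
load_codelist <- function(path, name = basename(path), version = "1") {
  ent <- data.table::fread(path, colClasses = "character", na.strings = NULL)
  required <- c("code", "system", "category", "site")
  missing <- setdiff(required, names(ent))
  if (length(missing)) {
    stop("codelist schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  }
  ent <- ent[, required, with = FALSE]
  make_codelist(ent, name = name, version = version)
}

#' Construct a codelist from a data frame
#'
#' @param entries data frame with columns `code`, `system`, `category`,
#'   `site` (empty string or `NA` = no site).
#' @inheritParams load_codelist
#' @return A `codelist` object.
#' @export
make_codelist <- function(entries, name = "codelist", version = "1") {
  ent <- data.table::as.data.table(entries)
  ent[, code := as.character(code)]
  ent[, system := as.character(system)]
  ent[, category := as.character(category)]
  ent[, site := as.character(site)]
  ent[site == "" | is.na(site), site := NA_character_]

  bad_sys <- setdiff(unique(ent$system), .code_systems)
  if (length(bad_sys)) {
    stop("codelist validation error: unknown system(s) ",
         paste(bad_sys, collapse = ", "))
  }
  if (anyDuplicated(ent, by = c("code", "system"))) {
    dup <- ent[duplicated(ent, by = c("code", "system"))]
    stop("codelist validation error: duplicate (code, system) pair(s): ",
         paste(unique(paste0(dup$code, "/", dup$system)), collapse = ", "))
  }
  if (any(ent$category == "" | is.na(ent$category))) {
    stop("codelist validation error: empty category")
  }
  bleed <- ent$category == "bleeding"
  if (any(bleed & is.na(ent$site))) {
    stop("codelist validation error: bleeding entry without anatomical site")
  }
  if (any(bleed & !ent$site %in% .bleeding_sites)) {
    stop("codelist validation error: unknown bleeding site; expected one of ",
         paste(.bleeding_sites, collapse = ", "))
  }
  if (any(!bleed & !is.na(ent$site))) {
    stop("codelist validation error: non-bleeding entry with a site")
  }

  ent[, norm := normalise_code(code, system)]
  if (anyDuplicated(ent, by = c("norm", "system"))) {
    dup <- ent[duplicated(ent, by = c("norm", "system"))]
    stop("codelist validation error: codes collide after normalisation: ",
         paste(unique(paste0(dup$code, "/", dup$system)), collapse = ", "))
  }
  for (sys in c("readlike", "icd10")) {
    if (!any(bleed & ent$system == sys)) {
      warning("codelist has no bleeding entries for system '", sys,
              "'; bleeding phenotyping will miss that source", call. = FALSE)
    }
  }
  data.table::setkeyv(ent, c("system", "norm"))
  structure(list(name = name, version = version, entries = ent[]),
            class = "codelist")
}

#' @export
print.codelist <- function(x, ...) {
  cat("<codelist>", x$name, "v", x$version, "-", nrow(x$entries), "entries\n")
  print(x$entries[, .N, by = category][order(-N)], nrows = 50)
  invisible(x)
}

#' Classify clinical codes against a codelist
#'
#' Looks up codes by exact match on the normalised form; for `icd10` and
#' `opcs4` codes with no exact hit, falls back to the longest listed prefix
#' of at least 3 characters (ICD/OPCS lists are commonly maintained at
#' 3-character block level). Unmatched codes yield `NA` category and site.
#' Exact matches always take precedence over prefix matches.
#'
#' @param codelist a `codelist` object.
#' @param code character vector of codes to classify.
#' @param system character vector of code systems, recycled against `code`.
#' @return A `data.table` with one row per input code and columns
#'   `category` and `site` (both `NA` for unmatched codes).
#' @export
classify_code <- function(codelist, code, system) {
  stopifnot(inherits(codelist, "codelist"))
  code <- as.character(code)
  system <- rep_len(as.character(system), length(code))
  if (!length(code)) {
    return(data.table(category = character(), site = character()))
  }
  q <- data.table(norm = normalise_code(code, system), system = system)
  ent <- codelist$entries
  hit <- ent[q, on = c("system", "norm"),
             .(category = x.category, site = x.site)]
  # longest-prefix fallback for hierarchical systems, minimum length 3
  remaining <- which(is.na(hit$category) & q$system %in% c("icd10", "opcs4"))
  if (length(remaining)) {
    lens <- sort(unique(nchar(ent$norm)), decreasing = TRUE)
    for (L in lens[lens >= 3]) {
      cand <- remaining[nchar(q$norm[remaining]) > L]  # strict prefix only
      if (!length(cand)) next
      sub <- data.table(norm = substr(q$norm[cand], 1L, L),
                        system = q$system[cand])
      m <- ent[nchar(norm) == L][sub, on = c("system", "norm"),
                                 .(category = x.category, site = x.site)]
      got <- which(!is.na(m$category))
      if (length(got)) {
        hit$category[cand[got]] <- m$category[got]
        hit$site[cand[got]] <- m$site[got]
        remaining <- setdiff(remaining, cand[got])
        if (!length(remaining)) break
      }
    }
  }
  hit[]
}

#' Extract the codes of a category (and optionally a site)
#'
#' @param codelist a `codelist` object.
#' @param category category to select.
#' @param system optional code system filter.
#' @param site optional site filter (bleeding entries).
#' @return Character vector of codes (original, un-normalised form).
#' @export
codes_for <- function(codelist, category, system = NULL, site = NULL) {
  ent <- codelist$entries
  keep <- ent$category %in% category
  if (!is.null(system)) keep <- keep & ent$system %in% system
  if (!is.null(site)) keep <- keep & ent$site %in% site
  ent$code[keep]
}

#' The bundled illustrative codelist
#'
#' Loads the codelist shipped with the package. Its content is illustrative:
#' it covers every category and anatomical site the phenotyping rules
#' consult, in the same `code,system,category,site` schema a production
#' terminology list would use, so a real list can be dropped in via
#' [load_codelist()]. It is not a clinically curated terminology.
#'
#' @return A `codelist` object.
#' @export
default_codelist <- function() {
  path <- system.file("extdata", "illustrative_codelist.csv",
                      package = "bleedpheno", mustWork = TRUE)
  load_codelist(path, name = "illustrative", version = "1")
}
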