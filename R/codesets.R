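# Code-set registry: named sets of diagnosis, drug-class and procedure code
# patterns with explicit matching semantics. Every code list used by the case
# definition is data (a YAML config), not code, so sites can swap in their own
# lists without touching the engine.

REGISTRY_DX_SETS <- c("dx_diabetes_primary_inpatient", "dx_diabetes_general",
                      "dx_pcos", "dx_menses_abnormal")
REGISTRY_DRUG_SETS <- c("drug_insulin", "drug_insulin_adjunct",
                        "drug_oral_hypoglycemic")
REGISTRY_PROC_SETS <- c("proc_diabetes_management", "proc_glycosylated_hemoglobin",
                        "proc_diabetes_related")
REGISTRY_SETS <- c(REGISTRY_DX_SETS, REGISTRY_DRUG_SETS, REGISTRY_PROC_SETS)

#' Normalize a clinical code string
#'
#' Strips all whitespace, upper-cases, and removes a single embedded decimal
#' point (ICD-9-CM codes are conventionally printed dotted, e.g. `250.13`, but
#' stored decimal-free in claims extracts, e.g. `25013`).
#'
#' @param code Character vector of raw code strings.
#' @return Character vector of normalized codes.
#' @export
#' @examples
#' normalize_code(c("250.13", " v58.67 "))
normalize_code <- function(code) {
  x <- gsub("[[:space:]]+", "", as.character(code))
  x <- toupper(x)
  sub(".", "", x, fixed = TRUE)
}

# TRUE for patterns that some other pattern in the same set strictly extends.
# Such patterns are treated as exact matches: a set listing both "250" and
# "2500" enumerates which fourth-digit subcategories of family 250 it covers,
# so the bare "250" stands only for the 3-digit code itself. A set listing
# "250" alone covers the whole family.
refined_in_set <- function(patterns) {
  vapply(patterns, function(p) {
    any(patterns != p & startsWith(patterns, p))
  }, logical(1), USE.NAMES = FALSE)
}

#' Match a code against a pattern set
#'
#' Matching is performed on normalized, decimal-free strings. A pattern
#' matches a code that equals it, or that extends it by trailing characters
#' (prefix semantics, patterns of length >= 3 only) -- unless the set also
#' contains a deeper pattern extending it, in which case the shorter pattern
#' matches exactly. Thus `{"250"}` matches `250.13`, while the restricted
#' inpatient list `{"250", "250.0", ..., "250.9"}` does not match `250.41`.
#'
#' @param pattern_set Character vector of code patterns (raw; normalized
#'   internally).
#' @param code Character vector of raw codes.
#' @return Logical vector, one element per code.
#' @export
#' @examples
#' match_code("250", "250.13")
#' match_code(c("250", "2500", "2501", "2502", "2503", "2509"), "250.41")
.pattern_cache <- new.env(parent = emptyenv())

# Normalized patterns + exact-only flags for a pattern set, memoized (the
# engine matches the same handful of sets millions of times).
compiled_patterns <- function(pattern_set) {
  key <- paste0("k", paste(pattern_set, collapse = "\r"))
  hit <- .pattern_cache[[key]]
  if (!is.null(hit)) return(hit)
  pats <- normalize_code(pattern_set)
  pats <- pats[nzchar(pats)]
  cp <- list(pats = pats, exact_only = refined_in_set(pats) | nchar(pats) < 3L)
  .pattern_cache[[key]] <- cp
  cp
}

match_code <- function(pattern_set, code) {
  cp <- compiled_patterns(pattern_set)
  pats <- cp$pats
  codes <- normalize_code(code)
  if (any(!nzchar(codes))) {
    bad <- which(!nzchar(codes))
    stop("malformed code: empty after normalization at position(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(pats) == 0L) return(rep(FALSE, length(codes)))
  out <- rep(FALSE, length(codes))
  for (i in seq_along(pats)) {
    p <- pats[i]
    if (cp$exact_only[i]) {
      out <- out | codes == p
    } else {
      out <- out | startsWith(codes, p)
    }
  }
  out
}

# Does set `big` accept every code accepted by set `small`? Used to enforce
# the registry's nesting invariants.
set_covers <- function(big, small) {
  big <- normalize_code(big)
  small <- normalize_code(small)
  exact_small <- refined_in_set(small) | nchar(small) < 3L
  exact_big <- refined_in_set(big) | nchar(big) < 3L
  all(vapply(seq_along(small), function(i) {
    p <- small[i]
    if (exact_small[i]) {
      # only the literal code p must be accepted
      any(big == p | (!exact_big & startsWith(p, big)))
    } else {
      # p and all its extensions must be accepted: need a prefix-capable
      # pattern of big at or above p
      any(!exact_big & startsWith(p, big))
    }
  }, logical(1)))
}

validate_registry <- function(reg) {
  missing <- setdiff(REGISTRY_SETS, names(reg))
  if (length(missing) > 0L) {
    stop("code registry config is missing required set(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in REGISTRY_SETS) {
    v <- as.character(reg[[nm]])
    if (length(v) == 0L || any(!nzchar(gsub("[[:space:]]", "", v)))) {
      stop("code registry set '", nm, "' must be a non-empty list of ",
           "non-empty code strings", call. = FALSE)
    }
    if (nm %in% REGISTRY_DX_SETS || nm %in% REGISTRY_PROC_SETS) {
      reg[[nm]] <- unique(normalize_code(v))
    } else {
      reg[[nm]] <- unique(gsub("[[:space:]]+", "", v))
    }
  }
  if (!set_covers(reg$dx_diabetes_general, reg$dx_diabetes_primary_inpatient)) {
    stop("registry invariant violated: dx_diabetes_primary_inpatient must be ",
         "a subset of dx_diabetes_general", call. = FALSE)
  }
  if (!set_covers(reg$proc_diabetes_management, reg$proc_glycosylated_hemoglobin)) {
    stop("registry invariant violated: proc_glycosylated_hemoglobin must be ",
         "a subset of proc_diabetes_management", call. = FALSE)
  }
  structure(reg[c("name", REGISTRY_SETS)], class = "code_registry")
}

#' Load a code registry from a YAML config
#'
#' The packaged default config (`codesets_default.yaml`) carries the shipped
#' code lists: the restricted diabetes family for primary inpatient discharge
#' diagnoses (250, 250.0-250.3, 250.9), the full 250 family for all other
#' diagnosis pathways, polycystic ovarian syndrome (256.4), absent/irregular
#' menses (626.0, 626.1, 626.4), drug-class labels, and procedure codes for
#' glycosylated hemoglobin (83036) and glucose testing. A user config needs to
#' list only the sets it overrides.
#'
#' @param config_path Path to a YAML file overriding any registry set, or
#'   `NULL` for the packaged defaults.
#' @return A `code_registry` object (validated named list of pattern sets).
#' @export
#' @examples
#' reg <- load_registry()
#' reg$dx_pcos
load_registry <- function(config_path = NULL) {
  default_path <- system.file("extdata", "codesets_default.yaml",
                              package = "dmphenotype", mustWork = TRUE)
  reg <- yaml::read_yaml(default_path)
  if (!is.null(config_path)) {
    if (!file.exists(config_path)) {
      stop("registry config not found: ", config_path, call. = FALSE)
    }
    override <- yaml::read_yaml(config_path)
    unknown <- setdiff(names(override), c("name", REGISTRY_SETS))
    if (length(unknown) > 0L) {
      stop("unknown registry set(s) in config: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    reg[names(override)] <- override
  }
  validate_registry(reg)
}

#' Packaged default code registry
#'
#' @return A `code_registry` with the shipped default code sets.
#' @export
default_registry <- function() load_registry(NULL)

#' @export
print.code_registry <- function(x, ...) {
  cat("<code_registry>", x$name %||% "unnamed", "\n")
  for (nm in REGISTRY_SETS) {
    cat(sprintf("  %-30s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
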