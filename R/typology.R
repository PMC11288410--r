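# Closed trait vocabulary of the paradigmatic classification, in the fixed
# order used to compose type codes. Cardinalities 3/2/6/3/5 span a
# 540-cell paradigm; only observed combinations become types.
TRAIT_LEVELS <- list(
  shape             = c("Tra", "Tri", "Seg"),
  symmetry          = c("S", "As"),
  edge_form         = c("R", "Cc", "Cv", "RCc", "RCv", "CcCv"),
  retouch_mode      = c("A", "S", "AS"),
  retouch_direction = c("D", "Al", "B", "Db", "I")
)

#' Trait vocabulary of the paradigmatic classification
#'
#' Returns the closed vocabulary for the five categorical trait dimensions
#' used to classify geometric microliths: shape (trapeze `Tra`, triangle
#' `Tri`, segment `Seg`), symmetry (`S`/`As`), edge form (straight,
#' concave, convex and their combinations), retouch mode (abrupt, simple,
#' combined) and retouch direction (direct, alternate, bifacial, double
#' bevel, inverse). The cross-product of the dimensions defines a
#' 540-cell paradigmatic space.
#'
#' @return Named list of character vectors, one per trait dimension, in
#'   the order used to compose type codes.
#' @export
#' @examples
#' trait_vocabulary()
trait_vocabulary <- function() {
  TRAIT_LEVELS
}

check_traits <- function(traits) {
  dims <- names(TRAIT_LEVELS)
  miss <- setdiff(dims, names(traits))
  if (length(miss) > 0L) {
    stop("missing trait column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (d in dims) {
    v <- as.character(traits[[d]])
    bad <- which(is.na(v) | !(v %in% TRAIT_LEVELS[[d]]))
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s code '%s' (row %d)", d, v[bad[1L]], bad[1L]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Encode trait tuples as composite paradigmatic type codes
#'
#' A type code is the hyphen-separated concatenation of the five trait
#' codes in fixed order shape-symmetry-edge_form-retouch_mode-
#' retouch_direction, e.g. `"Tra-As-RCc-A-D"`. Encoding is a bijection
#' with the trait 5-tuple; [decode_type()] inverts it exactly.
#'
#' @param traits A data frame (or named list) with character columns
#'   `shape`, `symmetry`, `edge_form`, `retouch_mode`,
#'   `retouch_direction`. All values must belong to [trait_vocabulary()];
#'   out-of-vocabulary or missing values raise an error naming the row
#'   and dimension.
#' @return Character vector of type codes, one per row.
#' @seealso [decode_type()], [build_type_inventory()]
#' @export
#' @examples
#' encode_type(data.frame(shape = "Tra", symmetry = "As", edge_form = "RCc",
#'                        retouch_mode = "A", retouch_direction = "D"))
encode_type <- function(traits) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  check_traits(traits)
  do.call(paste, c(lapply(traits[names(TRAIT_LEVELS)], as.character),
                   list(sep = "-")))
}

#' Decode composite type codes back to trait tuples
#'
#' @param type_code Character vector of codes produced by [encode_type()].
#' @return Data frame with the five trait columns; `decode_type(encode_type(x))`
#'   is identical to `x` for every cell of the paradigm.
#' @export
decode_type <- function(type_code) {
  parts <- strsplit(as.character(type_code), "-", fixed = TRUE)
  nbad <- which(lengths(parts) != length(TRAIT_LEVELS))
  if (length(nbad) > 0L) {
    stop(sprintf("malformed type code '%s' (element %d)",
                 type_code[nbad[1L]], nbad[1L]), call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- names(TRAIT_LEVELS)
  check_traits(out)
  out
}

#' Read an artefact assemblage table
#'
#' Reads a CSV with one artefact per row and columns
#' `site_id,level_id,shape,symmetry,edge_form,retouch_mode,
#' retouch_direction` (plus an optional free-text `source_note`), checks
#' every trait against the closed vocabulary, and attaches the composite
#' `type_code` and a `context` id (`"site:level"`).
#'
#' @param path Path to the CSV file.
#' @return Data frame of artefact records with `type_code` and `context`
#'   columns appended.
#' @export
read_assemblage <- function(path) {
  if (!file.exists(path)) {
    stop("assemblage file not found: ", path, call. = FALSE)
  }
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "level_id", names(TRAIT_LEVELS))
  miss <- setdiff(need, names(rec))
  if (length(miss) > 0L) {
    stop("assemblage file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rec) == 0L) stop("assemblage file has no records", call. = FALSE)
  rec$type_code <- encode_type(rec)
  rec$context <- paste(rec$site_id, rec$level_id, sep = ":")
  rec
}

#' Build the inventory of observed paradigmatic types
#'
#' Tallies the distinct composite types observed in a set of artefact
#' records. Counts conserve the record total: the counts over all types
#' sum to `nrow(records)`.
#'
#' @param records Data frame of artefact records carrying a `type_code`
#'   column (see [read_assemblage()] / [encode_type()]).
#' @return Data frame `type_code,count,shared` sorted by decreasing
#'   count; `shared` is `TRUE` when the type occurs more than once.
#' @export
build_type_inventory <- function(records) {
  if (is.null(records$type_code)) {
    stop("records must carry a 'type_code' column", call. = FALSE)
  }
  if (nrow(records) == 0L) {
    stop("cannot build a type inventory from zero records", call. = FALSE)
  }
  tab <- table(records$type_code)
  inv <- data.frame(type_code = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  inv$shared <- inv$count > 1L
  inv <- inv[order(-inv$count, inv$type_code), , drop = FALSE]
  rownames(inv) <- NULL
  inv
}

#' Keep only types observed more than once
#'
#' Applies the shared-type filter: types with a global count of 1 carry
#' no information about contact between contexts and are dropped together
#' with their records. Contexts whose records are all singleton types
#' disappear from downstream matrices. The filter is idempotent.
#'
#' @param inventory Type inventory from [build_type_inventory()].
#' @param records The records the inventory was built from.
#' @return List with elements `types` (the kept inventory rows) and
#'   `records` (the kept records).
#' @export
filter_shared_types <- function(inventory, records) {
  keep <- inventory[inventory$shared, , drop = FALSE]
  rownames(keep) <- NULL
  kept <- records[records$type_code %in% keep$type_code, , drop = FALSE]
  rownames(kept) <- NULL
  list(types = keep, records = kept)
}

#' Write a type inventory to CSV
#'
#' @param inventory Data frame from [build_type_inventory()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_type_inventory <- function(inventory, path) {
  utils::write.csv(inventory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
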