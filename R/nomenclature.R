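#' Parse a lipid shorthand name into a sum-composition species
#'
#' Resolves a species name written in any of the accepted shorthand dialects
#' to a subclass code plus a sum composition (total acyl/backbone carbons and
#' double-bond equivalents). Accepted forms include sum-level names
#' (\code{"PC 38:4"}, \code{"PC(38:4)"}), chain-level names with \code{"/"},
#' \code{"_"} or space separators (\code{"PC 18:0/20:4"}), optional
#' double-bond position or stereo annotations in parentheses (stripped),
#' legacy class synonyms (\code{"DAG(16:0/20:1(Z11))"} is \code{DG 36:1}),
#' sphingoid dialects (\code{"SM d18:1/20:4"}, \code{"Cer 18:1;O2/16:0"}),
#' and ether prefixes (\code{"PC O-34:1"} or \code{"O-PC 34:1"}; a
#' plasmalogen \code{"P-"} prefix is normalised to \code{"O-"} with one extra
#' double-bond equivalent).
#'
#' Chain-level compositions are summed over all listed chains; for
#' sphingolipids this is the sphingoid base plus the N-acyl chain. A
#' \code{"d"}/\code{"t"} sphingoid prefix contributes hydroxyl count only,
#' never extra double bonds; \code{";On"} suffixes are recorded as oxygens.
#'
#' Parsing is total: malformed names never raise an error, they return
#' \code{status = "unrecognised"} with a reason.
#'
#' @param raw_name a single lipid name.
#' @param registry character vector of known subclass codes; defaults to the
#'   codes of the packaged reaction database. Pass \code{NULL} to accept any
#'   syntactically valid subclass token.
#' @return an object of class \code{parsed_lipid}: a list with elements
#'   \code{raw_name}, \code{subclass}, \code{carbons}, \code{double_bonds},
#'   \code{oxygens}, \code{status} (\code{"parsed"} or
#'   \code{"unrecognised"}) and \code{rejection_reason}.
#' @seealso [canonical_label()], [parse_lipids()]
#' @examples
#' parse_lipid("PC 18:0/20:4(5Z,8Z,11Z,14Z)")  # PC(38:4)
#' parse_lipid("DAG(16:0/20:1(Z11))")          # DG(36:1)
#' parse_lipid("DG(aa-34:0")                   # unrecognised
#' @export
parse_lipid <- function(raw_name, registry = default_registry()) {
  stopifnot(is.character(raw_name), length(raw_name) == 1L)
  rejected <- function(reason) {
    structure(list(raw_name = raw_name, subclass = NA_character_,
                   carbons = NA_integer_, double_bonds = NA_integer_,
                   oxygens = NA_integer_, status = "unrecognised",
                   rejection_reason = reason),
              class = "parsed_lipid")
  }
  name <- trimws(raw_name)
  if (!nzchar(name)) return(rejected("empty name"))

  # split subclass token from composition: "PC(...)", "PC ...", "DAG(...)"
  subclass <- NA_character_
  comp_str <- NA_character_
  m <- regexec("^([A-Za-z][A-Za-z0-9-]*)\\s*\\((.*)\\)$", name)
  hit <- regmatches(name, m)[[1]]
  if (length(hit) == 3L) {
    subclass <- hit[2]; comp_str <- hit[3]
  } else {
    m <- regexec("^(\\S+)\\s+(\\S.*)$", name)
    hit <- regmatches(name, m)[[1]]
    if (length(hit) == 3L) {
      subclass <- hit[2]; comp_str <- hit[3]
    } else {
      return(rejected("non-conventional nomenclature"))
    }
  }
  syn <- c(DAG = "DG", TAG = "TG", MAG = "MG")
  if (subclass %in% names(syn)) subclass <- unname(syn[subclass])

  # strip positional/stereo annotations: innermost "(...)" groups, repeatedly
  prev <- ""
  while (!identical(prev, comp_str)) {
    prev <- comp_str
    comp_str <- gsub("\\([^()]*\\)", "", comp_str)
  }
  if (grepl("[()]", comp_str)) return(rejected("non-conventional nomenclature"))
  comp_str <- trimws(comp_str)
  if (!nzchar(comp_str)) return(rejected("missing composition"))

  chains <- strsplit(comp_str, "[/_[:space:]]+")[[1]]
  chains <- chains[nzchar(chains)]
  if (!length(chains)) return(rejected("missing composition"))

  carbons <- 0L; dbonds <- 0L; oxygens <- 0L; ether <- FALSE
  chain_re <- "^(O-|P-)?([dtm])?([0-9]+):([0-9]+)(;O([0-9]*))?$"
  for (ch in chains) {
    cm <- regmatches(ch, regexec(chain_re, ch))[[1]]
    if (!length(cm)) return(rejected("non-conventional nomenclature"))
    carbons <- carbons + as.integer(cm[4])
    dbonds <- dbonds + as.integer(cm[5])
    if (cm[2] == "O-") ether <- TRUE
    if (cm[2] == "P-") { ether <- TRUE; dbonds <- dbonds + 1L }
    # hydroxyl bookkeeping: d = di-, t = tri-hydroxy sphingoid base
    if (cm[3] == "d") oxygens <- oxygens + 2L
    if (cm[3] == "t") oxygens <- oxygens + 3L
    if (cm[3] == "m") oxygens <- oxygens + 1L
    if (nzchar(cm[6])) {
      n_ox <- if (nzchar(cm[7])) as.integer(cm[7]) else 1L
      oxygens <- oxygens + n_ox
    }
  }
  if (ether && !startsWith(subclass, "O-")) subclass <- paste0("O-", subclass)
  if (carbons < 1L && dbonds >= 1L) return(rejected("invalid composition"))
  if (!is.null(registry) && !(subclass %in% registry)) {
    return(rejected(sprintf("subclass '%s' not in registry", subclass)))
  }
  structure(list(raw_name = raw_name, subclass = subclass,
                 carbons = carbons, double_bonds = dbonds,
                 oxygens = oxygens, status = "parsed",
                 rejection_reason = NA_character_),
            class = "parsed_lipid")
}

#' Parse a vector of lipid names
#'
#' Vectorised front end to [parse_lipid()].
#'
#' @inheritParams parse_lipid
#' @param raw_names character vector of lipid names.
#' @return a data.frame with one row per input name and columns
#'   \code{raw_name}, \code{subclass}, \code{carbons}, \code{double_bonds},
#'   \code{oxygens}, \code{status}, \code{rejection_reason}, \code{label}
#'   (canonical label, \code{NA} for unrecognised names).
#' @export
parse_lipids <- function(raw_names, registry = default_registry()) {
  rows <- lapply(raw_names, function(nm) {
    p <- parse_lipid(nm, registry = registry)
    data.frame(raw_name = p$raw_name, subclass = p$subclass,
               carbons = p$carbons, double_bonds = p$double_bonds,
               oxygens = p$oxygens, status = p$status,
               rejection_reason = p$rejection_reason,
               label = if (p$status == "parsed") canonical_label(p) else NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Canonical label of a parsed lipid
#'
#' Deterministic rendering \code{"<subclass>(<C>:<D>)"}, e.g.
#' \code{"PC(34:0)"} or \code{"O-PC(34:0)"}. Two species with equal subclass
#' and sum composition always produce identical labels.
#'
#' @param p a \code{parsed_lipid} with \code{status = "parsed"}.
#' @return a single string.
#' @export
canonical_label <- function(p) {
  stopifnot(inherits(p, "parsed_lipid"))
  if (!identical(p$status, "parsed")) {
    stop("cannot label an unrecognised lipid: ", p$rejection_reason)
  }
  make_label(p$subclass, p$carbons, p$double_bonds)
}

make_label <- function(subclass, carbons, double_bonds) {
  sprintf("%s(%d:%d)", subclass, as.integer(carbons), as.integer(double_bonds))
}

# split "PC(34:0)" into its parts; used by the reaction database for the
# composition-specific FA entries and by graph round-trips
split_label <- function(label) {
  m <- regmatches(label, regexec("^(.*)\\(([0-9]+):([0-9]+)\\)$", label))[[1]]
  if (!length(m)) return(NULL)
  list(subclass = m[2], carbons = as.integer(m[3]), double_bonds = as.integer(m[4]))
}

default_registry <- function() {
  db <- load_reaction_db()
  db$subclasses$code
}

#' @export
print.parsed_lipid <- function(x, ...) {
  if (x$status == "parsed") {
    cat(sprintf("<parsed_lipid> %s  [from '%s']\n", canonical_label(x), x$raw_name))
  } else {
    cat(sprintf("<parsed_lipid> unrecognised '%s': %s\n", x$raw_name, x$rejection_reason))
  }
  invisible(x)
}
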