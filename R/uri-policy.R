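#' Default namespace table
#'
#' Prefix-to-base-IRI bindings used throughout the conversion: the common
#' vocabularies (BIBO, ChEBI, CHEMINF/SIO, CiTO, OBO/PRO, BFO), the legacy
#' `chembl:` term namespace, and the resource prefixes under which activity,
#' assay, molecule, document-resource and target IRIs are minted.  Standard
#' W3C prefixes (rdf, rdfs, owl, xsd, skos, dcterms) are bound as well so
#' that serializations stay readable.
#'
#' @return Named character vector mapping prefix to base IRI.
#' @export
default_namespaces <- function() {
  c(
    bibo    = "http://purl.org/ontology/bibo/",
    chebi   = "http://purl.org/obo/owl/CHEBI#",
    cheminf = "http://semanticscience.org/resource/",
    cito    = "http://purl.org/spar/cito/",
    obo     = "http://purl.obolibrary.org/obo/",
    bfo     = "http://www.ifomis.org/bfo/1.1/snap#",
    chembl  = "http://rdf.farmbio.uu.se/chembl/onto/#",
    act     = "http://linkedchemistry.info/chembl/activity/",
    assay   = "http://linkedchemistry.info/chembl/assay/",
    mol     = "http://linkedchemistry.info/chembl/molecule/",
    res     = "http://linkedchemistry.info/chembl/resource/",
    target  = "http://linkedchemistry.info/chembl/target/",
    rdf     = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs    = "http://www.w3.org/2000/01/rdf-schema#",
    owl     = "http://www.w3.org/2002/07/owl#",
    xsd     = "http://www.w3.org/2001/XMLSchema#",
    skos    = "http://www.w3.org/2004/02/skos/core#",
    dcterms = "http://purl.org/dc/terms/"
  )
}

# resource kinds that can be minted, and the prefix each one uses
.kind_prefix <- c(
  activity = "act",
  assay    = "assay",
  molecule = "mol",
  resource = "res",
  target   = "target"
)

.legacy_from <- "http://linkedchemistry.info/chembl/"
.legacy_to   <- "http://data.kasabi.com/dataset/chembl-rdf/"

#' URI minting policy
#'
#' Bundles the namespace table with the rules for building IRIs: the minting
#' mode (`"canonical"` uses the linkedchemistry.info bases; `"legacy"`
#' rewrites them onto the historical data.kasabi.com/dataset/chembl-rdf
#' pattern), the base for InChI-derived external IRIs together with a length
#' cap (SPARQL endpoint software commonly rejects very long URIs, so
#' InChI-based links are only built for smaller molecules), and the alias
#' table used when translating between proxy URL path segments and resource
#' namespaces.
#'
#' @param mode `"canonical"` or `"legacy"`.
#' @param namespaces Named character vector of prefix/base-IRI pairs; must
#'   contain at least the prefixes in [default_namespaces()].
#' @param inchi_uri_base Base IRI to which the percent-encoded InChI is
#'   appended.
#' @param max_uri_length Maximum length (characters) of an InChI-derived IRI;
#'   longer ones are suppressed.
#' @param proxy_aliases Named character vector mapping URL path segments to
#'   resource kinds, used by [translate_for_proxy()] in the backward
#'   direction.  Includes the historical `article` alias for the activity
#'   namespace.
#' @return An object of class `uri_policy`.
#' @export
uri_policy <- function(mode = c("canonical", "legacy"),
                       namespaces = default_namespaces(),
                       inchi_uri_base = "http://rdf.openmolecules.net/?InChI=",
                       max_uri_length = 2000L,
                       proxy_aliases = c(
                         activity = "activity", article = "activity",
                         assay = "assay", molecule = "molecule",
                         resource = "resource", target = "target"
                       )) {
  mode <- match.arg(mode)
  stopifnot(is.character(namespaces), !is.null(names(namespaces)))
  missing <- setdiff(names(default_namespaces()), names(namespaces))
  if (length(missing) > 0) {
    stop("namespace table is missing required prefixes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- namespaces[!grepl("[/#]$", namespaces)]
  if (length(bad) > 0) {
    stop("namespace base IRIs must end in '/' or '#': ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(max_uri_length) || max_uri_length <= 0) {
    stop("max_uri_length must be a positive integer", call. = FALSE)
  }
  structure(
    list(
      mode = mode,
      namespaces = namespaces,
      inchi_uri_base = inchi_uri_base,
      max_uri_length = as.integer(max_uri_length),
      proxy_aliases = proxy_aliases
    ),
    class = "uri_policy"
  )
}

#' @export
print.uri_policy <- function(x, ...) {
  cat("<uri_policy> mode:", x$mode,
      "| namespaces:", length(x$namespaces),
      "| max InChI IRI length:", x$max_uri_length, "\n")
  invisible(x)
}

#' Read a URI policy from a plain-text config file
#'
#' Each non-comment line holds a prefix and a base IRI separated by
#' whitespace.  Entries override the defaults; prefixes not mentioned keep
#' their default binding.
#'
#' @param path Path to the config file.
#' @param ... Passed on to [uri_policy()].
#' @return A `uri_policy`.
#' @export
read_uri_policy <- function(path, ...) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ns <- default_namespaces()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2) {
      stop("malformed policy line (want 'prefix base-iri'): ", ln, call. = FALSE)
    }
    ns[parts[1]] <- parts[2]
  }
  uri_policy(namespaces = ns, ...)
}

# namespace base for a kind, with the legacy host/path rewrite applied
.kind_base <- function(policy, kind) {
  prefix <- .kind_prefix[[kind]]
  base <- policy$namespaces[[prefix]]
  if (policy$mode == "legacy") {
    base <- sub(.legacy_from, .legacy_to, base, fixed = TRUE)
  }
  base
}

#' Percent-encode a string per RFC 3986
#'
#' Encodes, bytewise over the UTF-8 representation, every character outside
#' the RFC 3986 unreserved set plus any characters listed in `safe`.
#'
#' @param x Character vector.
#' @param safe Additional characters to leave unencoded.
#' @return Character vector of the same length.
#' @export
percent_encode <- function(x, safe = "") {
  safe_chars <- c(
    letters, LETTERS, as.character(0:9), "-", ".", "_", "~",
    strsplit(safe, "")[[1]]
  )
  vapply(enc2utf8(x), function(s) {
    if (is.na(s)) return(NA_character_)
    bytes <- charToRaw(s)
    out <- vapply(as.integer(bytes), function(b) {
      ch <- rawToChar(as.raw(b))
      if (b < 128L && ch %in% safe_chars) ch else sprintf("%%%02X", b)
    }, character(1))
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Decode a percent-encoded string
#'
#' @param x Character vector.
#' @return Character vector with `%XX` escapes resolved (UTF-8 aware).
#' @export
percent_decode <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    # decode bytewise, then reinterpret the byte string as UTF-8
    parts <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- raw(0)
    i <- 1L
    n <- length(parts)
    while (i <= n) {
      if (parts[i] == "%" && i + 2L <= n) {
        out <- c(out, as.raw(strtoi(paste0(parts[i + 1L], parts[i + 2L]), 16L)))
        i <- i + 3L
      } else {
        out <- c(out, charToRaw(parts[i]))
        i <- i + 1L
      }
    }
    enc <- rawToChar(out)
    Encoding(enc) <- "UTF-8"
    enc
  }, character(1), USE.NAMES = FALSE)
}

#' Mint a resource IRI
#'
#' Builds the IRI for a local identifier under the namespace of the given
#' resource kind.  Reserved URI characters in the identifier are
#' percent-encoded, never truncated.  Vectorized over `local_id`.
#'
#' @param kind One of `"activity"`, `"assay"`, `"molecule"`, `"resource"`,
#'   `"target"`.
#' @param local_id Character vector of local identifiers (non-empty, no
#'   whitespace).
#' @param policy A [uri_policy()].
#' @return Character vector of IRIs.
#' @export
#' @examples
#' mint_uri("activity", "a31863")
#' mint_uri("molecule", "ChEMBL406142")
mint_uri <- function(kind, local_id, policy = uri_policy()) {
  kind <- match.arg(kind, names(.kind_prefix))
  if (length(local_id) == 0) return(character(0))
  if (any(is.na(local_id) | !nzchar(local_id))) {
    stop("local_id must be non-empty", call. = FALSE)
  }
  if (any(grepl("\\s", local_id))) {
    stop("local_id must not contain whitespace: ",
         paste(local_id[grepl("\\s", local_id)], collapse = ", "),
         call. = FALSE)
  }
  paste0(.kind_base(policy, kind), percent_encode(as.character(local_id)))
}

#' Build an InChI-based external IRI
#'
#' Appends the percent-encoded InChI to the policy's InChI base.  The
#' characters `=/?,()` that structure InChI layers are left readable.
#' Returns `NA` (no link) when the resulting IRI would exceed the policy's
#' length cap, so identity links are only created for smaller molecules.
#' A string not starting with `"InChI="` is an error, not `NA`: invalid
#' input is distinguished from an overlong identifier.
#'
#' @param inchi Character vector of InChI strings.
#' @param policy A [uri_policy()].
#' @return Character vector of IRIs, `NA` where the cap is exceeded.
#' @export
inchi_uri <- function(inchi, policy = uri_policy()) {
  if (any(is.na(inchi)) || !all(startsWith(inchi, "InChI="))) {
    stop("not an InChI (must start with 'InChI='): ",
         paste(utils::head(inchi[is.na(inchi) | !startsWith(inchi, "InChI=")], 3),
               collapse = ", "),
         call. = FALSE)
  }
  iri <- paste0(policy$inchi_uri_base, percent_encode(inchi, safe = "=/?,()"))
  iri[nchar(iri) > policy$max_uri_length] <- NA_character_
  iri
}

#' Translate IRIs between canonical form and a local proxy
#'
#' A dereferencing proxy serves resources under its own base URL while the
#' triple store holds canonical IRIs.  `direction = "forward"` rewrites a
#' canonical IRI to `local_base` + path segment + local id;
#' `direction = "backward"` resolves a proxied URL back to the canonical
#' IRI, honouring the policy's path-segment alias table (so e.g. an
#' `article/` path may resolve into the activity namespace).  Forward then
#' backward is the identity on every minted IRI.
#'
#' @param uri IRI to translate.
#' @param local_base Base URL of the proxy, ending in `/`.
#' @param direction `"forward"` or `"backward"`.
#' @param policy A [uri_policy()].
#' @return Translated IRI.
#' @export
translate_for_proxy <- function(uri, local_base,
                                direction = c("forward", "backward"),
                                policy = uri_policy()) {
  direction <- match.arg(direction)
  if (!grepl("/$", local_base)) {
    stop("local_base must end in '/'", call. = FALSE)
  }
  if (direction == "forward") {
    for (kind in names(.kind_prefix)) {
      base <- .kind_base(policy, kind)
      if (startsWith(uri, base)) {
        return(paste0(local_base, kind, "/", substring(uri, nchar(base) + 1L)))
      }
    }
    stop("URI is not in any registered resource namespace: ", uri,
         call. = FALSE)
  }
  if (!startsWith(uri, local_base)) {
    stop("URL is not under the proxy base ", local_base, ": ", uri,
         call. = FALSE)
  }
  rest <- substring(uri, nchar(local_base) + 1L)
  parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !nzchar(parts[2])) {
    stop("proxy URL must have the form <base><segment>/<id>: ", uri,
         call. = FALSE)
  }
  kind <- unname(policy$proxy_aliases[parts[1]])
  if (is.null(kind) || is.na(kind)) {
    stop("unknown proxy path segment '", parts[1], "' in ", uri, call. = FALSE)
  }
  mint_uri(kind, percent_decode(parts[2]), policy)
}
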