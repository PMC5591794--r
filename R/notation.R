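#' @include AllClasses.R profile.R
NULL

## Strip the separators the published typography uses ("_", spaces, hyphens)
## while keeping, for every surviving character, its offset in the original
## string so parse errors can cite it.
.stripSeparators <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  keep <- !(chars %in% c("_", " ", "-", "\t"))
  list(chars = chars[keep], offsets = which(keep))
}

.parseError <- function(msg, offset) {
  stop(sprintf("uDISE parse error at character %d: %s", offset, msg),
       call. = FALSE)
}

#' Parse a uDISE score string
#'
#' Reads the compact notation (e.g. `N0V1APTs0O0Tb0E0L0`) or the separated
#' form with underscores, spaces or hyphens between tokens. Sites must appear
#' in canonical order N, V, Ts, O, Tb, E, L; after each degree the parser
#' greedily tries an optional configuration and backtracks if the next
#' expected site code cannot then be matched (this resolves the lateral-`L`
#' versus larynx-`L` ambiguity, e.g. in `...E2LL0`). A configuration given
#' at degree 0 is accepted and retained on the profile, although canonical
#' serialization omits it.
#'
#' @param text A single score string.
#' @return A [UdiseProfile-class].
#' @examples
#' parseUdise("N0V0Ts2LO0Tb2APE0L0")
#' parseUdise("N_0_V_1AP_Ts_0_O_0_Tb_0_E_0_L_0_")
#' @export
parseUdise <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("text must be a single character string", call. = FALSE)
  }
  s <- .stripSeparators(text)
  chars <- s$chars; off <- s$offsets
  n <- length(chars)
  pos <- 1L
  at <- function(p) if (p <= n) off[p] else nchar(text) + 1L
  matchLit <- function(lit, p) {
    k <- nchar(lit)
    if (p + k - 1L > n) return(FALSE)
    paste(chars[p:(p + k - 1L)], collapse = "") == lit
  }
  sites <- .STRUCTURES$code
  findings <- vector("list", 7L)
  for (i in seq_len(7L)) {
    code <- sites[i]
    if (!matchLit(code, pos)) {
      .parseError(sprintf("expected site '%s'%s", code,
                          if (pos <= n) sprintf(", found '%s'", chars[pos])
                          else " but input ended"),
                  at(pos))
    }
    pos <- pos + nchar(code)
    if (pos > n || !chars[pos] %in% c("0", "1", "2")) {
      .parseError(sprintf("expected degree 0-2 for site '%s'", code),
                  at(pos))
    }
    degree <- as.integer(chars[pos])
    pos <- pos + 1L
    cfg <- NA_character_
    allowed <- .ALLOWED_CONFIGS[[code]]
    if (length(allowed)) {
      ## try configurations longest-first; accept only if what follows still
      ## parses as the next expected site (or end of input after site 7)
      for (cand in c("AP", "C", "L")) {
        if (!cand %in% allowed || !matchLit(cand, pos)) next
        after <- pos + nchar(cand)
        okNext <- if (i < 7L) {
          matchLit(sites[i + 1L], after) &&
            {p2 <- after + nchar(sites[i + 1L]);
             p2 <= n && chars[p2] %in% c("0", "1", "2")}
        } else after > n
        if (okNext) { cfg <- cand; pos <- after; break }
      }
    }
    findings[[i]] <- tryCatch(
      siteFinding(code, degree, cfg),
      error = function(e) .parseError(conditionMessage(e), at(pos - 1L)))
  }
  if (pos <= n) {
    .parseError(sprintf("unexpected trailing input '%s'",
                        paste(chars[pos:n], collapse = "")), at(pos))
  }
  ## degree >= 1 with required configuration missing, etc., surface here
  udiseProfile(findings)
}

#' Serialize a uDISE profile
#'
#' Produces the canonical compact score string: sites in canonical order,
#' each site code followed by its degree and, only at degree >= 1, its
#' configuration. Degree-0 configurations a profile may carry internally are
#' not serialized.
#'
#' @param profile A [UdiseProfile-class].
#' @param sep Optional separator placed between site tokens (e.g. `"_"` or
#'   `" "`); the default `""` is the canonical compact form.
#' @return A single character string.
#' @examples
#' formatUdise(profileFromDegrees(c(E = 2), c(E = "AP")))
#' @export
formatUdise <- function(profile, sep = "") {
  stopifnot(is(profile, "UdiseProfile"))
  toks <- vapply(profile@findings, function(f) {
    cfg <- if (f@degree >= 1L && !is.na(f@configuration)) f@configuration
           else ""
    paste0(f@structure, f@degree, cfg)
  }, character(1))
  paste(toks, collapse = sep)
}

## ---- foreign tokens --------------------------------------------------------

#' Construct a foreign-system finding token
#'
#' @param system One of `foreignSystems()`.
#' @param site Site code within the system; omit for Pringle grades.
#' @param grade Integer grade; omit for the NOHL larynx.
#' @param flag `"N"` or `"P"` for the NOHL larynx.
#' @param configuration System-specific configuration code (`AP`, `L`, `C`,
#'   or NOHL transversal `t`), where the site defines one.
#' @return A validated [ForeignToken-class].
#' @examples
#' foreignToken("VOTE", site = "O", grade = 2, configuration = "L")
#' foreignToken("PRINGLE", grade = 3)
#' foreignToken("NOHL", site = "L", flag = "P")
#' @export
foreignToken <- function(system, site = NA_character_, grade = NA_integer_,
                         flag = NA_character_,
                         configuration = NA_character_) {
  new("ForeignToken", system = as.character(system),
      site = as.character(site), grade = as.integer(grade),
      flag = as.character(flag), configuration = as.character(configuration))
}

#' Render a foreign token in the package's compact token grammar
#'
#' Pringle: `G1`..`G5`; VOTE: site + `k` + grade + configuration (`Vk2AP`);
#' NOHL: site + configuration + grade (`Ot4`, `HAP3`), bare grade for nose
#' and tonsils (`N3`, `Ts4`), `LN`/`LP` for the larynx; P-T-L-Tb-E: site +
#' grade (`Tb2`). The published notation uses subscripts; this one-line
#' grammar is a package convenience, and the structured record form is
#' authoritative in files.
#'
#' @param token A [ForeignToken-class].
#' @return A single character string.
#' @export
formatForeignToken <- function(token) {
  stopifnot(is(token, "ForeignToken"))
  switch(token@system,
    PRINGLE = paste0("G", token@grade),
    VOTE = paste0(token@site, "k", token@grade,
                  if (!is.na(token@configuration)) token@configuration
                  else ""),
    NOHL = if (token@site == "L") paste0("L", token@flag)
           else paste0(token@site,
                       if (!is.na(token@configuration)) token@configuration
                       else "",
                       token@grade),
    PTLTBE = paste0(token@site, token@grade)
  )
}

#' Parse foreign-system score tokens
#'
#' Splits `text` on whitespace and/or commas and parses each piece in the
#' grammar of [formatForeignToken()]. VOTE accepts the `k` subscript marker
#' optionally (`Vk2AP` or `V2AP`) and allows the configuration to be absent
#' at grade 0.
#'
#' @param system One of `foreignSystems()`.
#' @param text Token string(s), e.g. `"Vk2AP Ok1L Tk2AP Ek0"`.
#' @return A list of validated [ForeignToken-class] objects.
#' @examples
#' parseForeign("NOHL", "N3 Ot4 HAP3 LP")
#' parseForeign("PRINGLE", "G3")
#' @export
parseForeign <- function(system, text) {
  spec <- .systemSpec(system)
  pieces <- unlist(strsplit(trimws(text), "[,[:space:]]+"))
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) stop("no tokens found in ", deparse(text),
                            call. = FALSE)
  lapply(pieces, function(p) .parseOneForeign(system, p))
}

.parseOneForeign <- function(system, piece) {
  bad <- function() stop(sprintf("cannot parse %s token '%s'", system, piece),
                         call. = FALSE)
  tok <- switch(system,
    PRINGLE = {
      m <- regmatches(piece, regexec("^G([0-9]+)\\+?$", piece))[[1]]
      if (!length(m)) bad()
      foreignToken("PRINGLE", grade = as.integer(m[2]))
    },
    VOTE = {
      m <- regmatches(piece,
                      regexec("^([VOTE])k?([0-9])(AP|L|C)?$", piece))[[1]]
      if (!length(m)) bad()
      foreignToken("VOTE", site = m[2], grade = as.integer(m[3]),
                   configuration = if (nzchar(m[4])) m[4] else NA_character_)
    },
    NOHL = {
      if (grepl("^L[NP]$", piece)) {
        foreignToken("NOHL", site = "L", flag = substring(piece, 2L, 2L))
      } else {
        m <- regmatches(piece,
                        regexec("^(Ts|N|O|H)(AP|t|L|C)?([0-9])$",
                                piece))[[1]]
        if (!length(m)) bad()
        foreignToken("NOHL", site = m[2], grade = as.integer(m[4]),
                     configuration = if (nzchar(m[3])) m[3] else NA_character_)
      }
    },
    PTLTBE = {
      m <- regmatches(piece, regexec("^(Tb|Ts|P|T|L|E)([0-9])$", piece))[[1]]
      if (!length(m)) bad()
      foreignToken("PTLTBE", site = m[2], grade = as.integer(m[3]))
    },
    stop("unknown classification system: ", system, call. = FALSE)
  )
  tok
}

setMethod("show", "ForeignToken", function(object) {
  cat(sprintf("ForeignToken %s: %s\n", object@system,
              formatForeignToken(object)))
})
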