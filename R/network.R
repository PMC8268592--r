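#' Construct a metabolic network
#'
#' A `scour_network` couples the stoichiometric topology of a metabolic
#' system (each reaction's primary substrate and products) with the
#' ground-truth controller sets used for evaluation. Controllers are the
#' metabolites that appear in the functional form of a reaction's rate: the
#' primary substrate (always, with positive sign) plus any allosteric
#' regulators with sign `+1` (activation) or `-1` (inhibition).
#'
#' @param metabolites character vector of unique metabolite identifiers.
#' @param reactions list of reaction specifications, each a list with
#'   elements `id`, `substrate` (metabolite id or `NA` for an influx),
#'   `products` (character vector, possibly empty), `constant` (logical;
#'   constant fluxes have no controllers), and `controllers` (a named
#'   numeric vector of signs, names are metabolite ids; empty for constant
#'   reactions).
#' @param name optional label for the network.
#'
#' @return An object of class `scour_network` with elements `name`,
#'   `metabolites` and `reactions`.
#' @export
#' @examples
#' net <- scour_network(
#'   metabolites = c("A", "B"),
#'   reactions = list(
#'     list(id = "v1", substrate = NA, products = "A", constant = TRUE,
#'          controllers = numeric()),
#'     list(id = "v2", substrate = "A", products = "B", constant = FALSE,
#'          controllers = c(A = 1))
#'   ),
#'   name = "toy"
#' )
#' print(net)
scour_network <- function(metabolites, reactions, name = "network") {
  metabolites <- as.character(metabolites)
  if (anyDuplicated(metabolites)) {
    stop("metabolite ids must be unique", call. = FALSE)
  }
  reactions <- lapply(reactions, function(r) {
    r$id <- as.character(r$id)
    r$constant <- isTRUE(r$constant)
    if (is.null(r$products)) r$products <- character()
    r$products <- as.character(r$products)
    ctrl <- r$controllers
    if (is.null(ctrl)) ctrl <- numeric()
    if (length(ctrl) && is.null(names(ctrl))) {
      stop("controllers must be a named sign vector", call. = FALSE)
    }
    r$controllers <- ctrl
    r
  })
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("reaction ids must be unique", call. = FALSE)
  net <- structure(
    list(name = name, metabolites = metabolites, reactions = reactions),
    class = "scour_network"
  )
  validate_network(net)
  net
}

validate_network <- function(net) {
  mets <- net$metabolites
  for (r in net$reactions) {
    if (!is.na(r$substrate) && !(r$substrate %in% mets)) {
      stop(sprintf("reaction %s: unknown substrate '%s'", r$id, r$substrate),
           call. = FALSE)
    }
    if (length(r$products) && !all(r$products %in% mets)) {
      stop(sprintf("reaction %s: unknown product", r$id), call. = FALSE)
    }
    cn <- names(r$controllers)
    if (r$constant) {
      if (length(r$controllers)) {
        stop(sprintf("constant reaction %s must have no controllers", r$id),
             call. = FALSE)
      }
    } else {
      if (!all(cn %in% mets)) {
        stop(sprintf("reaction %s: unknown controller", r$id), call. = FALSE)
      }
      if (anyDuplicated(cn)) {
        stop(sprintf("reaction %s: duplicate controllers", r$id), call. = FALSE)
      }
      if (!(r$substrate %in% cn) || r$controllers[[r$substrate]] != 1) {
        stop(sprintf(
          "reaction %s: primary substrate must be a controller with sign +1",
          r$id), call. = FALSE)
      }
      if (!all(r$controllers %in% c(-1, 1))) {
        stop(sprintf("reaction %s: controller signs must be +1 or -1", r$id),
             call. = FALSE)
      }
    }
  }
  invisible(net)
}

#' @export
print.scour_network <- function(x, ...) {
  cat(sprintf("<scour_network> %s: %d metabolites, %d reactions (%d constant)\n",
              x$name, length(x$metabolites), length(x$reactions),
              sum(vapply(x$reactions, `[[`, logical(1), "constant"))))
  for (r in x$reactions) {
    if (r$constant) {
      cat(sprintf("  %s: constant influx -> %s\n", r$id,
                  paste(r$products, collapse = "+")))
    } else {
      sgn <- ifelse(r$controllers > 0, "+", "-")
      cat(sprintf("  %s: %s -> %s  ctrl {%s}\n", r$id, r$substrate,
                  if (length(r$products)) paste(r$products, collapse = "+") else ".",
                  paste0(names(r$controllers), "(", sgn, ")", collapse = ", ")))
    }
  }
  invisible(x)
}

#' Reference synthetic networks
#'
#' Two fixed benchmark networks used throughout the package: a smaller
#' system (6 metabolites, 6 reactions) and a bigger one (10 metabolites,
#' 10 reactions). In both, `v1` is a constant influx not controlled by any
#' metabolite, and the remaining fluxes are controlled by one, two or three
#' metabolites with a mixture of activating and inhibiting regulation.
#' Per-order interaction counts: smaller has 1 one-controller, 2
#' two-controller and 2 three-controller fluxes; bigger has 3 of each.
#'
#' @param name `"smaller"` or `"bigger"`.
#' @return A [scour_network].
#' @export
#' @examples
#' reference_network("smaller")
reference_network <- function(name = c("smaller", "bigger")) {
  name <- match.arg(name)
  rx <- function(id, sub, prod, ctrl) {
    list(id = id, substrate = sub, products = prod, constant = FALSE,
         controllers = ctrl)
  }
  if (name == "smaller") {
    mets <- paste0("x", 1:6)
    reactions <- list(
      list(id = "v1", substrate = NA, products = "x1", constant = TRUE,
           controllers = numeric()),
      rx("v2", "x1", "x2", c(x1 = 1)),
      rx("v3", "x2", "x3", c(x2 = 1, x5 = -1)),
      rx("v4", "x3", "x4", c(x3 = 1, x1 = 1)),
      rx("v5", "x4", "x5", c(x4 = 1, x2 = 1, x3 = -1)),
      rx("v6", "x5", "x6", c(x5 = 1, x1 = -1, x4 = 1))
    )
  } else {
    mets <- paste0("x", 1:10)
    reactions <- list(
      list(id = "v1", substrate = NA, products = "x1", constant = TRUE,
           controllers = numeric()),
      rx("v2", "x1", "x2", c(x1 = 1)),
      rx("v3", "x2", "x3", c(x2 = 1)),
      rx("v4", "x3", "x4", c(x3 = 1)),
      rx("v5", "x4", "x5", c(x4 = 1, x7 = -1)),
      rx("v6", "x5", "x6", c(x5 = 1, x9 = 1)),
      rx("v7", "x6", "x7", c(x6 = 1, x2 = -1)),
      rx("v8", "x7", "x8", c(x7 = 1, x3 = 1, x10 = -1)),
      rx("v9", "x8", "x9", c(x8 = 1, x1 = 1, x5 = -1)),
      rx("v10", "x9", "x10", c(x9 = 1, x4 = -1, x6 = 1))
    )
  }
  scour_network(mets, reactions, name = name)
}

## --- helpers over the reaction list ------------------------------------

#' Reaction ids of a network
#'
#' @param net a [scour_network].
#' @param constant `NA` for all reactions, `TRUE` for constant fluxes
#'   only, `FALSE` for non-constant only.
#' @return Character vector of reaction ids.
#' @export
reaction_ids <- function(net, constant = NA) {
  keep <- vapply(net$reactions, function(r) {
    if (is.na(constant)) TRUE else r$constant == constant
  }, logical(1))
  vapply(net$reactions[keep], `[[`, character(1), "id")
}

get_reaction <- function(net, id) {
  for (r in net$reactions) if (r$id == id) return(r)
  stop(sprintf("unknown reaction id '%s'", id), call. = FALSE)
}

#' True controller order of each non-constant reaction
#'
#' @param net a [scour_network].
#' @return Named integer vector: number of controller metabolites per
#'   non-constant reaction.
#' @export
controller_orders <- function(net) {
  rs <- Filter(function(r) !r$constant, net$reactions)
  stats::setNames(vapply(rs, function(r) length(r$controllers), integer(1)),
                  vapply(rs, `[[`, character(1), "id"))
}

## --- serialization ------------------------------------------------------

network_to_list <- function(net) {
  list(
    name = net$name,
    metabolites = as.list(net$metabolites),
    reactions = lapply(net$reactions, function(r) {
      list(id = r$id,
           substrate = if (is.na(r$substrate)) NULL else r$substrate,
           products = as.list(r$products),
           constant = r$constant,
           controllers = if (length(r$controllers)) {
             lapply(seq_along(r$controllers), function(i) {
               list(metabolite = names(r$controllers)[i],
                    sign = unname(r$controllers[i]))
             })
           } else list())
    })
  )
}

list_to_network <- function(x) {
  reactions <- lapply(x$reactions, function(r) {
    ctrl <- numeric()
    if (length(r$controllers)) {
      ctrl <- stats::setNames(
        vapply(r$controllers, function(c) as.numeric(c$sign), numeric(1)),
        vapply(r$controllers, function(c) as.character(c$metabolite), character(1))
      )
    }
    list(id = r$id,
         # JSON serialises a missing substrate as {} -> empty list
         substrate = if (length(r$substrate) == 0) NA_character_ else
           as.character(r$substrate),
         products = unlist(r$products, use.names = FALSE),
         constant = isTRUE(r$constant),
         controllers = ctrl)
  })
  scour_network(unlist(x$metabolites, use.names = FALSE), reactions,
                name = if (is.null(x$name)) "network" else x$name)
}

#' Read / write a network specification file
#'
#' Networks are stored as YAML (or JSON) with keys `name`, `metabolites`
#' and `reactions`, each reaction a mapping with `id`, `substrate`,
#' `products`, `constant` and `controllers` (list of
#' `{metabolite, sign}`).
#'
#' @param path file path; format chosen by extension (`.json` for JSON,
#'   anything else is parsed as YAML).
#' @param net a [scour_network].
#' @return `read_network` returns a [scour_network]; `write_network`
#'   returns `path` invisibly.
#' @export
read_network <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  list_to_network(x)
}

#' @rdname read_network
#' @export
write_network <- function(net, path) {
  x <- network_to_list(net)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
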