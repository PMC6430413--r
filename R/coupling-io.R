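# ME-problem serialization: a documented JSON schema with (a, b) affine
# pairs per coefficient, bound and right-hand side. Deterministic output
# (two writes are byte-identical).

#' Write an ME problem as JSON
#'
#' Schema (`acetome_me_problem/1`): `variables` (id, kind, lb/ub as
#' `[a, b]` affine pairs evaluated as a + b*mu), `rows` (id, sense, rhs
#' pair), `coefficients` (row, col, a, b triplets).
#'
#' @param prob an `acetome_me_problem`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_me_problem <- function(prob, path) {
  doc <- list(
    schema = "acetome_me_problem/1",
    signature = prob$signature,
    variables = lapply(seq_along(prob$col_ids), function(j)
      list(id = prob$col_ids[j], kind = unname(prob$col_kind[j]),
           lb = c(prob$lb_a[j], prob$lb_b[j]),
           ub = c(prob$ub_a[j], prob$ub_b[j]))),
    rows = lapply(seq_along(prob$row_ids), function(i)
      list(id = prob$row_ids[i], sense = unname(prob$row_sense[i]),
           rhs = c(prob$rhs_a[i], prob$rhs_b[i]))),
    coefficients = lapply(seq_len(nrow(prob$trip)), function(k)
      list(row = prob$row_ids[prob$trip$i[k]],
           col = prob$col_ids[prob$trip$j[k]],
           a = prob$trip$a[k], b = prob$trip$b[k])))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}

#' Read an ME problem written by [write_me_problem()]
#'
#' Restores the growth-rate-parametric LP (variables, rows, affine
#' coefficients). Solver-facing fields only; generator metadata (gene/TU
#' maps, registry) is not serialized, so solution extraction helpers that
#' need it are unavailable on a round-tripped problem.
#'
#' @param path JSON file.
#' @return an `acetome_me_problem` (solver fields populated).
#' @export
read_me_problem <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$schema, "acetome_me_problem/1"))
    stop("not an acetome ME-problem file (schema mismatch)")
  col_ids <- vapply(doc$variables, `[[`, "", "id")
  row_ids <- vapply(doc$rows, `[[`, "", "id")
  getp <- function(x, f, k) vapply(x, function(e) e[[f]][[k]], 0)
  trip <- data.frame(
    i = match(vapply(doc$coefficients, `[[`, "", "row"), row_ids),
    j = match(vapply(doc$coefficients, `[[`, "", "col"), col_ids),
    a = vapply(doc$coefficients, `[[`, 0, "a"),
    b = vapply(doc$coefficients, `[[`, 0, "b"))
  structure(list(
    col_ids = col_ids,
    col_kind = vapply(doc$variables, `[[`, "", "kind"),
    lb_a = getp(doc$variables, "lb", 1), lb_b = getp(doc$variables, "lb", 2),
    ub_a = vapply(doc$variables, function(e) {
      v <- e$ub[[1]]; if (is.character(v) || is.null(v)) Inf else v
    }, 0),
    ub_b = getp(doc$variables, "ub", 2),
    row_ids = row_ids,
    row_sense = vapply(doc$rows, `[[`, "", "sense"),
    rhs_a = getp(doc$rows, "rhs", 1), rhs_b = getp(doc$rows, "rhs", 2),
    trip = trip, signature = doc$signature),
    class = "acetome_me_problem")
}
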