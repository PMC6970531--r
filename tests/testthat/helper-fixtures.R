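## small coordinate-file fixtures, built in code at test time

write_fixture_pdb <- function(path, rows) {
  ## rows: data.frame chain, resno, resid, elety, elesy, x, y, z, o, alt, het
  fmt <- "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s"
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    elety <- if (nchar(r$elety) < 4) paste0(" ", r$elety) else r$elety
    sprintf(fmt, if (isTRUE(r$het)) "HETATM" else "ATOM", i, elety,
            if (is.na(r$alt)) " " else r$alt, r$resid, r$chain, r$resno, " ",
            r$x, r$y, r$z, r$o, 0, r$elesy)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_fixture_cif <- function(path, rows) {
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                   "label_atom_id", "label_alt_id",
                                   "label_comp_id", "label_asym_id",
                                   "label_entity_id", "label_seq_id",
                                   "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                                   "Cartn_z", "occupancy", "B_iso_or_equiv",
                                   "auth_seq_id", "auth_comp_id",
                                   "auth_asym_id", "auth_atom_id",
                                   "pdbx_PDB_model_num")))
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    paste(if (isTRUE(r$het)) "HETATM" else "ATOM", i, r$elesy, r$elety,
          if (is.na(r$alt)) "." else r$alt, r$resid, r$chain, 1, r$resno, "?",
          sprintf("%.3f %.3f %.3f", r$x, r$y, r$z), r$o, "0.00",
          r$resno, r$resid, r$chain, r$elety, 1)
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

fixture_rows <- function(chain, resno, elety = "CA", resid = "ALA",
                         elesy = "C", x = 0, y = 0, z = 0, o = 1,
                         alt = NA_character_, het = FALSE) {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = x, y = y, z = z, o = o, alt = alt, het = het,
             stringsAsFactors = FALSE)
}
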