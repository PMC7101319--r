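#include <Rcpp.h>
using namespace Rcpp;

// Parse samtools pileup base/quality strings into quality-filtered base
// counts. One row per input line. Grammar handled:
//   '.' ','            reference base (either strand)
//   ACGTacgt           mismatching base call
//   '^' + mapq char    read start marker (both chars consumed, no base)
//   '$'                read end marker (no base)
//   '+n'/'-n' + n chars  indel run, skipped entirely (no quality chars)
//   '*' '>' '<' 'N' 'n'  placeholder calls: consume a quality char but are
//                        excluded from numerator and denominator
// Every counted or placeholder base symbol consumes exactly one quality
// char (Phred+33). A base/quality length mismatch after de-escaping is a
// parse error naming the 1-based line number.
//
// [[Rcpp::export]]
IntegerMatrix parse_pileup_calls(CharacterVector bases, CharacterVector quals,
                                 CharacterVector ref, int min_phred) {
  int n = bases.size();
  IntegerMatrix out(n, 6);
  colnames(out) = CharacterVector::create("A", "C", "G", "T",
                                          "filtered_depth", "raw_depth");
  for (int i = 0; i < n; ++i) {
    std::string b = as<std::string>(bases[i]);
    std::string q = as<std::string>(quals[i]);
    char r = toupper(as<std::string>(ref[i])[0]);
    int cnt[4] = {0, 0, 0, 0};
    int raw = 0;
    size_t qi = 0, bi = 0;
    while (bi < b.size()) {
      char c = b[bi];
      if (c == '^') {
        bi += 2;  // caret plus mapping-quality char
        continue;
      }
      if (c == '$') { ++bi; continue; }
      if (c == '+' || c == '-') {
        ++bi;
        size_t len = 0;
        if (bi >= b.size() || !isdigit(b[bi]))
          stop("malformed indel marker at line %d", i + 1);
        while (bi < b.size() && isdigit(b[bi])) {
          len = len * 10 + (b[bi] - '0');
          ++bi;
        }
        bi += len;  // inserted/deleted sequence carries no quality chars
        continue;
      }
      // every remaining symbol consumes one quality char
      if (qi >= q.size())
        stop("base/quality length mismatch at line %d", i + 1);
      int phred = static_cast<int>(q[qi]) - 33;
      ++qi;
      ++bi;
      char base;
      if (c == '.' || c == ',') base = r;
      else if (c == '*' || c == '>' || c == '<' || c == 'N' || c == 'n')
        continue;  // no base call: excluded from numerator and denominator
      else if (strchr("ACGTacgt", c)) base = toupper(c);
      else stop("unexpected pileup symbol '%c' at line %d", c, i + 1);
      ++raw;
      if (phred >= min_phred) {
        switch (base) {
          case 'A': ++cnt[0]; break;
          case 'C': ++cnt[1]; break;
          case 'G': ++cnt[2]; break;
          case 'T': ++cnt[3]; break;
          default: stop("unknown reference base at line %d", i + 1);
        }
      }
    }
    if (qi != q.size())
      stop("base/quality length mismatch at line %d", i + 1);
    out(i, 0) = cnt[0]; out(i, 1) = cnt[1];
    out(i, 2) = cnt[2]; out(i, 3) = cnt[3];
    out(i, 4) = cnt[0] + cnt[1] + cnt[2] + cnt[3];
    out(i, 5) = raw;
  }
  return out;
}
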