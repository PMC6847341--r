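#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Tokenize one samtools-mpileup base string against its quality string.
//
// Kind codes: 0 = reference match, 1 = substitution, 2 = insertion,
// 3 = deletion, 4 = N call (dropped before modelling, kept for counting).
//
// Grammar handled: "." / "," match (fwd/rev); "ACGTN" / "acgtn" mismatch;
// "^X" read start (X = mapping quality, consumed, no observation); "$" read
// end (no observation); "*" ("#" on reverse) deletion placeholder, consumes
// one quality char; "+n[seq]" / "-n[seq]" indel attached to the PRECEDING
// observation, which is upgraded to insertion/deletion (no quality char of
// its own); ">" / "<" reference skips occupy a depth slot and a quality
// char but yield no observation.
//
// [[Rcpp::export(name = ".tokenize_bases_cpp")]]
List tokenize_bases_cpp(const std::string& bases, const std::string& quals,
                        const std::string& ref_base, bool keep_bases) {
  const size_t n = bases.size();
  const size_t nq = quals.size();
  if (ref_base.empty()) stop("reference base must be a single character");
  const char refU = std::toupper(static_cast<unsigned char>(ref_base[0]));

  std::vector<int> kind, qual, rev;
  std::vector<std::string> obs_base;
  kind.reserve(nq); qual.reserve(nq); rev.reserve(nq);
  if (keep_bases) obs_base.reserve(nq);

  size_t qi = 0;
  size_t i = 0;
  while (i < n) {
    const char c = bases[i];
    if (c == '^') {
      if (i + 1 >= n) stop("dangling '^' with no mapping-quality character");
      i += 2;  // '^' + mapping quality char, no observation
      continue;
    }
    if (c == '$') { ++i; continue; }
    if (c == '>' || c == '<') {  // reference skip: quality slot, no observation
      if (qi >= nq) stop("quality string shorter than observation count");
      ++qi; ++i;
      continue;
    }
    if (c == '+' || c == '-') {  // indel attached to preceding observation
      size_t j = i + 1;
      long len = 0;
      bool have_digit = false;
      while (j < n && std::isdigit(static_cast<unsigned char>(bases[j]))) {
        len = len * 10 + (bases[j] - '0');
        ++j; have_digit = true;
      }
      if (!have_digit) stop("malformed indel token at offset %d", (int)i + 1);
      if (j + (size_t)len > n) stop("indel sequence truncated at offset %d", (int)i + 1);
      if (kind.empty()) stop("dangling indel token (no anchor observation)");
      const size_t a = kind.size() - 1;
      kind[a] = (c == '+') ? 2 : 3;
      if (keep_bases) {
        if (c == '+') {
          std::string seq = bases.substr(j, len);
          for (char& s : seq) s = std::toupper(static_cast<unsigned char>(s));
          obs_base[a] = seq;
        } else {
          obs_base[a] = "-";
        }
      }
      i = j + len;
      continue;
    }
    if (c == '.' || c == ',') {
      if (qi >= nq) stop("quality string shorter than observation count");
      kind.push_back(0);
      rev.push_back(c == ',');
      qual.push_back((int)(unsigned char)quals[qi++] - 33);
      if (keep_bases) obs_base.push_back(std::string(1, refU));
      ++i;
      continue;
    }
    if (c == '*' || c == '#') {
      if (qi >= nq) stop("quality string shorter than observation count");
      kind.push_back(3);
      rev.push_back(c == '#');
      qual.push_back((int)(unsigned char)quals[qi++] - 33);
      if (keep_bases) obs_base.push_back("-");
      ++i;
      continue;
    }
    const char u = std::toupper(static_cast<unsigned char>(c));
    if (u == 'A' || u == 'C' || u == 'G' || u == 'T' || u == 'N') {
      if (qi >= nq) stop("quality string shorter than observation count");
      const bool is_rev = std::islower(static_cast<unsigned char>(c)) != 0;
      int k;
      if (u == 'N') k = 4;
      else k = (u == refU) ? 0 : 1;
      kind.push_back(k);
      rev.push_back(is_rev);
      qual.push_back((int)(unsigned char)quals[qi++] - 33);
      if (keep_bases) obs_base.push_back(std::string(1, u));
      ++i;
      continue;
    }
    stop("unknown pileup character '%c' at offset %d", c, (int)i + 1);
  }
  if (qi != nq) stop("quality string longer than observation count");

  List out = List::create(
      _["kind"] = wrap(kind),
      _["qual"] = wrap(qual),
      _["reverse"] = wrap(rev));
  if (keep_bases) out["base"] = wrap(obs_base);
  return out;
}
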