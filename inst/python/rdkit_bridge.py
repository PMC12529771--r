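"""Batched RDKit worker for the latentmol R package.

Reads newline-delimited SMILES from an input file and writes one
tab-separated record per input line to an output file.  Three modes:

  process  raw SMILES -> curation fields + the 13 molecular properties
  canon    SMILES -> canonical SMILES ("" when unparseable)
  fp       SMILES -> 2048-bit Morgan fingerprint (radius 2) as set-bit indices

Usage: python rdkit_bridge.py <mode> <infile> <outfile>
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, QED

RDLogger.DisableLog("rdApp.*")

ORGANIC_ELEMENTS = {"H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"}

# Fixed property order shared with the R side (chemprep module).
PROPERTY_NAMES = [
    "MolWt", "MolLogP", "QED", "MinPartialCharge", "MaxPartialCharge",
    "NumValenceElectrons", "HeavyAtomCount", "NumHAcceptors", "NumHDonors",
    "LabuteASA", "BalabanJ", "MolMR", "TPSA",
]


def is_organic(mol):
    symbols = {a.GetSymbol() for a in mol.GetAtoms()}
    return "C" in symbols and symbols <= ORGANIC_ELEMENTS


def largest_organic_fragment(mol):
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    best, best_n = None, -1
    for f in frags:
        if is_organic(f) and f.GetNumHeavyAtoms() > best_n:
            best, best_n = f, f.GetNumHeavyAtoms()
    return best


def compute_properties(mol):
    return [
        Descriptors.MolWt(mol),
        Descriptors.MolLogP(mol),
        QED.qed(mol),
        Descriptors.MinPartialCharge(mol),
        Descriptors.MaxPartialCharge(mol),
        Descriptors.NumValenceElectrons(mol),
        Descriptors.HeavyAtomCount(mol),
        Descriptors.NumHAcceptors(mol),
        Descriptors.NumHDonors(mol),
        Descriptors.LabuteASA(mol),
        Descriptors.BalabanJ(mol),
        Descriptors.MolMR(mol),
        Descriptors.TPSA(mol),
    ]


def process_line(smi):
    """-> (status, canonical, properties or None)"""
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return "parse_error", "", None
    frag = largest_organic_fragment(mol)
    if frag is None:
        return "no_organic_fragment", "", None
    Chem.RemoveStereochemistry(frag)
    try:
        Chem.SanitizeMol(frag)
        canonical = Chem.MolToSmiles(frag, isomericSmiles=False)
        frag = Chem.MolFromSmiles(canonical)
        if frag is None:
            return "parse_error", "", None
        props = compute_properties(frag)
    except Exception:
        return "descriptor_error", "", None
    props = [float(p) for p in props]
    if any(p != p for p in props):  # NaN guard (e.g. charge computation)
        return "descriptor_error", canonical, None
    return "ok", canonical, props


def main():
    mode, infile, outfile = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(infile) as fh:
        lines = [ln.rstrip("\n") for ln in fh]
    out = []
    if mode == "process":
        for smi in lines:
            status, canonical, props = process_line(smi)
            fields = [""] * len(PROPERTY_NAMES) if props is None else \
                [repr(float(p)) for p in props]
            out.append("\t".join([status, canonical] + fields))
    elif mode == "canon":
        for smi in lines:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.append("")
            else:
                Chem.RemoveStereochemistry(mol)
                out.append(Chem.MolToSmiles(mol, isomericSmiles=False))
    elif mode == "fp":
        gen = AllChem.GetMorganGenerator(radius=2, fpSize=2048)
        for smi in lines:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.append("NA")
            else:
                bits = gen.GetFingerprint(mol).GetOnBits()
                out.append(",".join(str(b) for b in bits))
    else:
        sys.exit("unknown mode: " + mode)
    with open(outfile, "w") as fh:
        fh.write("\n".join(out) + ("\n" if out else ""))


if __name__ == "__main__":
    main()
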