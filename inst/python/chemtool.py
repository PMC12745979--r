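"""Batch cheminformatics helper.

Usage: python chemtool.py INFILE OUTFILE OP [OP ...]

INFILE holds one SMILES per line. OUTFILE receives one tab-separated row
per input line with one column per requested OP:

  valid     "1" / "0"
  canonical canonical nonisomeric SMILES ("" if unparseable)
  mw        average molecular weight in Da ("" if unparseable)
  scaffold  canonical nonisomeric Murcko scaffold; acyclic molecules fall
            back to the molecule itself ("" if unparseable)
  morgan    space-separated on-bit indices of the 2048-bit radius-2
            Morgan fingerprint ("" if unparseable)

Empty input lines yield empty/invalid rows rather than errors.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")

_MORGAN = rdFingerprintGenerator.GetMorganGenerator(radius=2, fpSize=2048)


def _nonisomeric(mol):
    return Chem.MolToSmiles(mol, isomericSmiles=False)


def _scaffold(mol):
    scaf = MurckoScaffold.GetScaffoldForMol(mol)
    if scaf is None or scaf.GetNumAtoms() == 0:
        return _nonisomeric(mol)
    return Chem.MolToSmiles(scaf, isomericSmiles=False)


def _fields(mol, ops):
    out = []
    for op in ops:
        if mol is None:
            out.append("0" if op == "valid" else "")
        elif op == "valid":
            out.append("1")
        elif op == "canonical":
            out.append(_nonisomeric(mol))
        elif op == "mw":
            out.append("%.6f" % Descriptors.MolWt(mol))
        elif op == "scaffold":
            out.append(_scaffold(mol))
        elif op == "morgan":
            out.append(" ".join(str(i) for i in _MORGAN.GetFingerprint(mol).GetOnBits()))
        else:
            raise SystemExit("unknown op: " + op)
    return out


def main(argv):
    infile, outfile, ops = argv[1], argv[2], argv[3:]
    if not ops:
        raise SystemExit("no ops requested")
    with open(infile) as fh, open(outfile, "w") as out:
        for line in fh:
            smi = line.rstrip("\n")
            mol = Chem.MolFromSmiles(smi) if smi else None
            out.write("\t".join(_fields(mol, ops)) + "\n")


if __name__ == "__main__":
    main(sys.argv)
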