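>Human
MQTSAMNAAFLKVPQLLKTFPCVPFGSFLDPRINIQRLLRPRWLRLSCVSLPDDCVYCPRARRLVHDEKASKRASFKTTTSAPSAISRPDSALLQPEESSSPSCPASYCRGWDVNSGPWSPCLRKSLQFLRGMTPPNGMITTHPLQDLSSPNLLRGLTVCNPVPSSTLHTRATV
>Chimpanzee
MQTSAMNAAFLKVPQPLKTFPCVPFGSFLDPRINIQRLLRPRWLRLSCVS--DDCVYCPRARRLVHDECASKRASFKCTTSAPSAISRPDSALLQPEESSSPSCPASYCRGWDVNSGPWSPCLRKSLQFLRGMTPPNGMITTHPLQDLSSGNLLRGLTVCNPVHSSTLHTRATV
>Mouse
MQTSAMNAAFLKVPQLLKTFPCVSFGRFLDPRINIQRLLRPRWLRLSCVSLPDDCVYCPRLRRLVH--KASKRASFKTTTSGPSAISRPCSALLQPEESSSPSCPASYCRGWVVNLGPWVLTLRMHLQFLRGMTPPNGMITWHDSQDLSSPNLLRGLTVCNPFPSSTLHTRATV
>Rat
MQTSAMNAAFLKVPQLLTTFPCNSFGSFLDPMINIQRLLRPRLNRLMCVSLPDDCCYCPRARRLVHDEKASKRASFKT--SAPWAISRPDSALLGPEESSSPSCPASYCRGWDVISGPWSPCLRCSLQFLRGMTGPNGMITTHPLQDGSSPNLLRGLTVCNPVPSSTLHTRATV
>Zebrafish
MQFSAMNAWWRKVPQLLKTFPMFTDGCFLDPRINIQRLWQPRWFRLSI--NPDSCVTCPRWRRLVHSEKESYIATFKTTTTAPSAISRFDSALLQPEEISSPSCPAGYCYKWDVNSGDWSPCLRELLQFLRGMTWPNGSITWHWLQDLSSPNLIRGPDVCNPAPSRTLPTRATV
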