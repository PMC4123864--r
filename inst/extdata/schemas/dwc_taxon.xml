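<?xml version="1.0" encoding="UTF-8"?>
<!-- Taxon Core: a Simple Darwin Core subset for checklist (taxon) records. -->
<extension title="Darwin Core Taxon"
           rowType="http://rs.tdwg.org/dwc/terms/Taxon"
           subject="dwc:taxonID">
  <property name="taxonID" qualName="http://rs.tdwg.org/dwc/terms/taxonID"/>
  <property name="scientificNameID" qualName="http://rs.tdwg.org/dwc/terms/scientificNameID"/>
  <property name="acceptedNameUsageID" qualName="http://rs.tdwg.org/dwc/terms/acceptedNameUsageID"/>
  <property name="parentNameUsageID" qualName="http://rs.tdwg.org/dwc/terms/parentNameUsageID"/>
  <property name="scientificName" qualName="http://rs.tdwg.org/dwc/terms/scientificName"/>
  <property name="acceptedNameUsage" qualName="http://rs.tdwg.org/dwc/terms/acceptedNameUsage"/>
  <property name="parentNameUsage" qualName="http://rs.tdwg.org/dwc/terms/parentNameUsage"/>
  <property name="higherClassification" qualName="http://rs.tdwg.org/dwc/terms/higherClassification"/>
  <property name="kingdom" qualName="http://rs.tdwg.org/dwc/terms/kingdom"/>
  <property name="phylum" qualName="http://rs.tdwg.org/dwc/terms/phylum"/>
  <property name="class" qualName="http://rs.tdwg.org/dwc/terms/class"/>
  <property name="order" qualName="http://rs.tdwg.org/dwc/terms/order"/>
  <property name="family" qualName="http://rs.tdwg.org/dwc/terms/family"/>
  <property name="genus" qualName="http://rs.tdwg.org/dwc/terms/genus"/>
  <property name="subgenus" qualName="http://rs.tdwg.org/dwc/terms/subgenus"/>
  <property name="specificEpithet" qualName="http://rs.tdwg.org/dwc/terms/specificEpithet"/>
  <property name="infraspecificEpithet" qualName="http://rs.tdwg.org/dwc/terms/infraspecificEpithet"/>
  <property name="taxonRank" qualName="http://rs.tdwg.org/dwc/terms/taxonRank"/>
  <property name="verbatimTaxonRank" qualName="http://rs.tdwg.org/dwc/terms/verbatimTaxonRank"/>
  <property name="scientificNameAuthorship" qualName="http://rs.tdwg.org/dwc/terms/scientificNameAuthorship"/>
  <property name="vernacularName" qualName="http://rs.tdwg.org/dwc/terms/vernacularName"/>
  <property name="nomenclaturalCode" qualName="http://rs.tdwg.org/dwc/terms/nomenclaturalCode"/>
  <property name="taxonomicStatus" qualName="http://rs.tdwg.org/dwc/terms/taxonomicStatus"/>
  <property name="nomenclaturalStatus" qualName="http://rs.tdwg.org/dwc/terms/nomenclaturalStatus"/>
  <property name="taxonRemarks" qualName="http://rs.tdwg.org/dwc/terms/taxonRemarks"/>
  <property name="modified" qualName="http://purl.org/dc/terms/modified"/>
  <property name="references" qualName="http://purl.org/dc/terms/references"/>
</extension>
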