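<?xml version="1.0" encoding="UTF-8"?>
<!-- Occurrence Core: a Simple Darwin Core subset for specimen/observation
     records.  Term subset transcribed once from the public core definition;
     property order is the canonical column order. -->
<extension title="Darwin Core Occurrence"
           rowType="http://rs.tdwg.org/dwc/terms/Occurrence"
           subject="dwc:occurrenceID">
  <property name="occurrenceID" qualName="http://rs.tdwg.org/dwc/terms/occurrenceID"/>
  <property name="basisOfRecord" qualName="http://rs.tdwg.org/dwc/terms/basisOfRecord"/>
  <property name="institutionCode" qualName="http://rs.tdwg.org/dwc/terms/institutionCode"/>
  <property name="collectionCode" qualName="http://rs.tdwg.org/dwc/terms/collectionCode"/>
  <property name="catalogNumber" qualName="http://rs.tdwg.org/dwc/terms/catalogNumber"/>
  <property name="otherCatalogNumbers" qualName="http://rs.tdwg.org/dwc/terms/otherCatalogNumbers"/>
  <property name="datasetName" qualName="http://rs.tdwg.org/dwc/terms/datasetName"/>
  <property name="recordedBy" qualName="http://rs.tdwg.org/dwc/terms/recordedBy"/>
  <property name="recordNumber" qualName="http://rs.tdwg.org/dwc/terms/recordNumber"/>
  <property name="individualCount" qualName="http://rs.tdwg.org/dwc/terms/individualCount"/>
  <property name="sex" qualName="http://rs.tdwg.org/dwc/terms/sex"/>
  <property name="lifeStage" qualName="http://rs.tdwg.org/dwc/terms/lifeStage"/>
  <property name="establishmentMeans" qualName="http://rs.tdwg.org/dwc/terms/establishmentMeans"/>
  <property name="occurrenceStatus" qualName="http://rs.tdwg.org/dwc/terms/occurrenceStatus"/>
  <property name="preparations" qualName="http://rs.tdwg.org/dwc/terms/preparations"/>
  <property name="associatedMedia" qualName="http://rs.tdwg.org/dwc/terms/associatedMedia"/>
  <property name="occurrenceRemarks" qualName="http://rs.tdwg.org/dwc/terms/occurrenceRemarks"/>
  <property name="eventID" qualName="http://rs.tdwg.org/dwc/terms/eventID"/>
  <property name="fieldNumber" qualName="http://rs.tdwg.org/dwc/terms/fieldNumber"/>
  <property name="eventDate" qualName="http://rs.tdwg.org/dwc/terms/eventDate"/>
  <property name="eventTime" qualName="http://rs.tdwg.org/dwc/terms/eventTime"/>
  <property name="year" qualName="http://rs.tdwg.org/dwc/terms/year"/>
  <property name="month" qualName="http://rs.tdwg.org/dwc/terms/month"/>
  <property name="day" qualName="http://rs.tdwg.org/dwc/terms/day"/>
  <property name="samplingProtocol" qualName="http://rs.tdwg.org/dwc/terms/samplingProtocol"/>
  <property name="habitat" qualName="http://rs.tdwg.org/dwc/terms/habitat"/>
  <property name="continent" qualName="http://rs.tdwg.org/dwc/terms/continent"/>
  <property name="waterBody" qualName="http://rs.tdwg.org/dwc/terms/waterBody"/>
  <property name="country" qualName="http://rs.tdwg.org/dwc/terms/country"/>
  <property name="countryCode" qualName="http://rs.tdwg.org/dwc/terms/countryCode"/>
  <property name="stateProvince" qualName="http://rs.tdwg.org/dwc/terms/stateProvince"/>
  <property name="county" qualName="http://rs.tdwg.org/dwc/terms/county"/>
  <property name="municipality" qualName="http://rs.tdwg.org/dwc/terms/municipality"/>
  <property name="locality" qualName="http://rs.tdwg.org/dwc/terms/locality"/>
  <property name="verbatimLocality" qualName="http://rs.tdwg.org/dwc/terms/verbatimLocality"/>
  <property name="minimumElevationInMeters" qualName="http://rs.tdwg.org/dwc/terms/minimumElevationInMeters"/>
  <property name="maximumElevationInMeters" qualName="http://rs.tdwg.org/dwc/terms/maximumElevationInMeters"/>
  <property name="decimalLatitude" qualName="http://rs.tdwg.org/dwc/terms/decimalLatitude"/>
  <property name="decimalLongitude" qualName="http://rs.tdwg.org/dwc/terms/decimalLongitude"/>
  <property name="geodeticDatum" qualName="http://rs.tdwg.org/dwc/terms/geodeticDatum"/>
  <property name="coordinateUncertaintyInMeters" qualName="http://rs.tdwg.org/dwc/terms/coordinateUncertaintyInMeters"/>
  <property name="georeferencedBy" qualName="http://rs.tdwg.org/dwc/terms/georeferencedBy"/>
  <property name="identifiedBy" qualName="http://rs.tdwg.org/dwc/terms/identifiedBy"/>
  <property name="dateIdentified" qualName="http://rs.tdwg.org/dwc/terms/dateIdentified"/>
  <property name="scientificName" qualName="http://rs.tdwg.org/dwc/terms/scientificName"/>
  <property name="scientificNameAuthorship" qualName="http://rs.tdwg.org/dwc/terms/scientificNameAuthorship"/>
  <property name="vernacularName" qualName="http://rs.tdwg.org/dwc/terms/vernacularName"/>
  <property name="kingdom" qualName="http://rs.tdwg.org/dwc/terms/kingdom"/>
  <property name="phylum" qualName="http://rs.tdwg.org/dwc/terms/phylum"/>
  <property name="class" qualName="http://rs.tdwg.org/dwc/terms/class"/>
  <property name="order" qualName="http://rs.tdwg.org/dwc/terms/order"/>
  <property name="family" qualName="http://rs.tdwg.org/dwc/terms/family"/>
  <property name="genus" qualName="http://rs.tdwg.org/dwc/terms/genus"/>
  <property name="specificEpithet" qualName="http://rs.tdwg.org/dwc/terms/specificEpithet"/>
  <property name="infraspecificEpithet" qualName="http://rs.tdwg.org/dwc/terms/infraspecificEpithet"/>
  <property name="taxonRank" qualName="http://rs.tdwg.org/dwc/terms/taxonRank"/>
  <property name="modified" qualName="http://purl.org/dc/terms/modified"/>
  <property name="license" qualName="http://purl.org/dc/terms/license"/>
  <property name="rightsHolder" qualName="http://purl.org/dc/terms/rightsHolder"/>
  <property name="accessRights" qualName="http://purl.org/dc/terms/accessRights"/>
</extension>
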